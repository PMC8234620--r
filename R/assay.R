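#' Percent inhibition from raw assay signals
#'
#' Blank-corrected activity ratio: `100 * (1 - (sample - blank) /
#' (control - blank))`. The control window (`control - blank`) must be
#' positive.
#'
#' @param sample_signal Signal with inhibitor present.
#' @param control_signal Signal of the uninhibited reaction.
#' @param blank Background signal (default 0).
#' @return Percent inhibition; 0 when the sample equals the control, 100
#'   when it equals the blank. Values below 0 (activation) or above 100
#'   are possible and preserved.
#' @export
#' @examples
#' percent_inhibition(0.6, 1.0, 0.2)  # 50
percent_inhibition <- function(sample_signal, control_signal, blank = 0) {
  if (any(control_signal - blank <= 0)) {
    stop("control window (control - blank) must be positive", call. = FALSE)
  }
  100 * (1 - (sample_signal - blank) / (control_signal - blank))
}

#' Read a dose-response table
#'
#' @param path TSV with columns `analyte`, `concentration`, `units`,
#'   `replicate`, `inhibition` (percent).
#' @return A tibble.
#' @export
read_dose_response <- function(path) {
  if (!file.exists(path)) {
    stop("dose-response file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("analyte", "concentration", "inhibition")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("dose-response table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Fit an IC50 from a dose-response curve
#'
#' The default estimator is the log-linear plot used for inhibition
#' assays read on a plate: percent inhibition is regressed on the base-10
#' logarithm of concentration, and the IC50 is the concentration at which
#' the fitted line crosses 50\%, `10^((50 - intercept) / slope)`.
#' Replicates are averaged per concentration before fitting (set
#' `aggregate = FALSE` to pool raw replicates instead). A logistic
#' alternative (`method = "logistic"`, two-parameter with the response
#' constrained to 0--100\%) is available for robustness comparisons.
#'
#' The fit is censored -- `value` is `NA` and `label` reports
#' `"> <c_max> <units>"` -- when the maximum observed mean inhibition stays
#' below 50\% at the highest tested concentration, or when the fitted
#' slope is not positive.
#'
#' @param curve A data frame with columns `concentration` and `inhibition`
#'   (percent), optionally `replicate`, `analyte` and `units`.
#' @param method `"loglinear"` (default) or `"logistic"`.
#' @param aggregate Average replicates per concentration before fitting
#'   (default `TRUE`).
#' @return An object of class `ic50_fit`: a list with `value` (IC50 in the
#'   curve's concentration units), `se` (delta-method standard error),
#'   `slope`, `intercept`, `r_squared`, `censored`, `c_max`, `label`,
#'   `n_points`, `method`, `analyte`, `units`.
#' @export
#' @examples
#' fit <- fit_ic50(data.frame(concentration = c(1, 10),
#'                            inhibition = c(25, 75)))
#' fit$value  # 10^0.5 = 3.162...
fit_ic50 <- function(curve, method = c("loglinear", "logistic"),
                     aggregate = TRUE) {
  method <- match.arg(method)
  conc <- curve$concentration
  inh <- curve$inhibition
  if (any(is.na(conc)) || any(conc <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  if (length(unique(conc)) < 2) {
    stop("need at least two distinct concentrations", call. = FALSE)
  }
  analyte <- if ("analyte" %in% names(curve)) unique(curve$analyte)[1] else NA_character_
  units <- if ("units" %in% names(curve)) unique(curve$units)[1] else ""
  if (aggregate) {
    agg <- tapply(inh, conc, mean)
    conc <- as.numeric(names(agg))
    inh <- as.numeric(agg)
  }
  c_max <- max(conc)
  label_censored <- trimws(paste0("> ", format(c_max, trim = TRUE), " ", units))
  out <- list(value = NA_real_, se = NA_real_, slope = NA_real_,
              intercept = NA_real_, r_squared = NA_real_, censored = FALSE,
              c_max = c_max, label = NA_character_,
              n_points = length(conc), method = method,
              analyte = analyte, units = units)
  lfit <- stats::lm(inh ~ log10(conc))
  b <- stats::coef(lfit)
  out$intercept <- unname(b[1])
  out$slope <- unname(b[2])
  ss_tot <- sum((inh - mean(inh))^2)
  out$r_squared <- if (ss_tot > 0) 1 - sum(stats::residuals(lfit)^2) / ss_tot else NA_real_
  if (max(inh) < 50) {
    out$censored <- TRUE
    out$label <- label_censored
    return(structure(out, class = "ic50_fit"))
  }
  if (method == "loglinear") {
    if (out$slope <= 0) {
      out$censored <- TRUE
      out$label <- paste0(label_censored, " (non-positive slope)")
      return(structure(out, class = "ic50_fit"))
    }
    g <- (50 - out$intercept) / out$slope
    out$value <- 10^g
    v <- suppressWarnings(stats::vcov(lfit))  # summary.lm warns on exact fits
    grad <- c(-1 / out$slope, -(50 - out$intercept) / out$slope^2)
    var_g <- drop(t(grad) %*% v %*% grad)
    if (is.finite(var_g) && var_g >= 0) {
      out$se <- log(10) * out$value * sqrt(var_g)
    }
  } else {
    # two-parameter logistic: inh = 100 / (1 + 10^(h * (log10(ic50) - log10(c))))
    # the log-linear fit seeds the logistic one; at the midpoint a logistic
    # with Hill slope h rises ~57.6 h percent per decade
    start <- list(lic50 = (50 - out$intercept) / max(out$slope, 1e-6),
                  h = max(out$slope, 1) / 57.6)
    nfit <- try(stats::nls(
      inh ~ 100 / (1 + 10^(h * (lic50 - log10(conc)))),
      start = start,
      # scaleOffset keeps the convergence test defined on noise-free curves
      control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
      silent = TRUE)
    if (inherits(nfit, "try-error")) {
      stop("logistic fit failed to converge; use method = 'loglinear'",
           call. = FALSE)
    }
    cf <- stats::coef(nfit)
    out$value <- 10^unname(cf["lic50"])
    se_l <- tryCatch(summary(nfit)$coefficients["lic50", "Std. Error"],
                     error = function(e) NA_real_)
    out$se <- log(10) * out$value * se_l
    resid <- inh - stats::predict(nfit)
    out$r_squared <- 1 - sum(resid^2) / sum((inh - mean(inh))^2)
  }
  out$label <- format(signif(out$value, 4), trim = TRUE)
  structure(out, class = "ic50_fit")
}

#' @export
print.ic50_fit <- function(x, ...) {
  who <- if (is.na(x$analyte)) "" else paste0(x$analyte, ": ")
  if (x$censored) {
    cat(who, "IC50 ", x$label, " (censored; max inhibition below 50%)\n",
        sep = "")
  } else {
    cat(who, "IC50 = ", format(signif(x$value, 4)),
        if (nzchar(x$units)) paste0(" ", x$units) else "",
        " (se ", format(signif(x$se, 3)),
        ", slope ", format(signif(x$slope, 3)), " %/decade",
        ", R2 ", format(signif(x$r_squared, 3)), ")\n", sep = "")
  }
  invisible(x)
}

#' Serving-size model: cheese needed to reach an IC50 in the gut
#'
#' A solid meal reaches the small intestine diluted roughly 8- to 10-fold
#' by digestive secretions. Taking a serving of `serving_mass` grams
#' diluted `dilution_factor`-fold as the reference intestinal volume (in
#' mL, at unit density), the peptide concentration delivered by `m` grams
#' of cheese is `m * peptide_content / (serving_mass * dilution_factor)`.
#' This function inverts that relation: the grams of cheese whose peptides
#' reach the extract's IC50 in the intestine,
#' `m = ic50 * serving_mass * dilution_factor / peptide_content`.
#'
#' @param ic50 Extract IC50 in mg/mL.
#' @param peptide_content Extractable peptide content of the cheese in
#'   mg per g.
#' @param serving_mass Reference serving in g (default 50).
#' @param dilution_factor Intestinal dilution fold (default 10).
#' @param round Round half-up to the nearest gram (default `TRUE`).
#' @return Grams of cheese.
#' @export
#' @examples
#' estimate_serving(1.90, 63.54)  # 15 g
#' estimate_serving(2.74, 63.54)  # 22 g
estimate_serving <- function(ic50, peptide_content, serving_mass = 50,
                             dilution_factor = 10, round = TRUE) {
  if (any(ic50 < 0) || any(peptide_content <= 0) || serving_mass <= 0 ||
      dilution_factor <= 0) {
    stop("all serving-model inputs must be positive", call. = FALSE)
  }
  grams <- ic50 * serving_mass * dilution_factor / peptide_content
  if (round) round_half_up(grams) else grams
}
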