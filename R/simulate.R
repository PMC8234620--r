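#' Simulate a ripening-structured peptidome
#'
#' Emulates the cross-sample structure of a cheese peptidome followed over
#' ripening: a core of peptides shared by every sample plus sample-unique
#' peptides, with per-sample precursor composition drifting over time.
#' Peptides are sampled as random substrings of real mature casein chains
#' (not random strings), so every generated record passes
#' [validate_assignments()] by construction and precursor-incidence
#' statistics are meaningful. Sample-unique peptides are drawn disjointly
#' after the shared core, which makes the all-samples Venn region exactly
#' `n_core`.
#'
#' Defaults mirror the marginals reported for Parmigiano-Reggiano sampled
#' at 12/18/24/30 months: per-sample totals 283 and 312 at the ends with
#' the unreported middle totals linearly interpolated (293, 302), a shared
#' core of 228 peptides, and beta-casein incidence drifting from about
#' 49.5\% down to 45.5\%.
#'
#' @param precursors Precursor tibble; defaults to the bundled mature
#'   caseins.
#' @param samples Tibble with columns `sample`, `ripening_months`,
#'   `total` (peptidome sizes).
#' @param n_core Number of peptides shared by all samples. Overridden by
#'   `core_fraction` when that is given.
#' @param core_fraction Alternatively, the target all-samples share of the
#'   union; the core count is the integer closest to satisfying
#'   `core = f * union`. Because per-sample totals are held exact, the
#'   realised core can deviate from `f * union` by up to
#'   `(1 + f * (n_samples - 1)) / 2` peptides -- within one peptide for
#'   moderate fractions.
#' @param weights Matrix of per-sample precursor mixture weights
#'   (`n_samples` rows summing to 1, columns named by precursor); defaults
#'   to the ripening drift described above.
#' @param length_range Min/max peptide length (default `c(3, 25)`, the
#'   span seen in low-molecular-weight extracts below 3 kDa).
#' @param length_mode Mode of the triangular length distribution
#'   (default 8).
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A peptide table tibble (one row per peptide; its drawn
#'   assignment and sample membership), with the realised configuration in
#'   `attr(, "sim_config")`.
#' @export
#' @examples
#' peps <- simulate_peptidome(seed = 1)
#' lengths(peptide_sets(peps))
simulate_peptidome <- function(precursors = NULL,
                               samples = tibble::tibble(
                                 sample = c("PR12", "PR18", "PR24", "PR30"),
                                 ripening_months = c(12L, 18L, 24L, 30L),
                                 total = c(283L, 293L, 302L, 312L)),
                               n_core = 228L,
                               core_fraction = NULL,
                               weights = NULL,
                               length_range = c(3L, 25L),
                               length_mode = 8L,
                               seed = 1L) {
  precursors <- precursors %||%
    read_precursors(pepscreen_extdata("caseins_mature.fasta"))
  k <- nrow(samples)
  stopifnot(k >= 1, all(samples$total > 0))
  if (!is.null(core_fraction)) {
    stopifnot(core_fraction >= 0, core_fraction <= 1)
    # with sample-unique non-core peptides, union = total - (k-1) * core;
    # pick the integer core minimising |core - f * union(core)|
    c_star <- core_fraction * sum(samples$total) /
      (1 + core_fraction * (k - 1))
    cand <- unique(c(floor(c_star), ceiling(c_star)))
    dev <- abs(cand - core_fraction * (sum(samples$total) - (k - 1) * cand))
    n_core <- cand[which.min(dev)]
  }
  n_core <- as.integer(n_core)
  if (n_core > min(samples$total)) {
    stop("shared core (", n_core, ") larger than the smallest sample (",
         min(samples$total), ")", call. = FALSE)
  }
  if (is.null(weights)) {
    # beta-casein dominates and declines with ripening; alphaS1 grows
    months <- samples$ripening_months
    t01 <- if (length(unique(months)) > 1) {
      (months - min(months)) / (max(months) - min(months))
    } else rep(0, k)
    beta <- 0.495 - 0.040 * t01
    as1 <- 0.304 + 0.052 * t01
    as2 <- 1 - beta - as1
    weights <- cbind(`beta-casein` = beta, `alphaS1-casein` = as1,
                     `alphaS2-casein` = as2)
  }
  stopifnot(nrow(weights) == k,
            all(abs(rowSums(weights) - 1) < 1e-8),
            all(colnames(weights) %in% precursors$name))
  if (max(length_range) > max(nchar(precursors$sequence))) {
    stop("requested peptide lengths exceed the precursor lengths",
         call. = FALSE)
  }
  set.seed(as.integer(seed))

  draw_batch <- function(n, w) {
    len <- draw_triangular(n, length_range[1], length_range[2], length_mode)
    prob <- w[1, match(precursors$name, colnames(w))]
    prob[is.na(prob)] <- 0
    prec_idx <- sample.int(nrow(precursors), n, replace = TRUE, prob = prob)
    plen <- nchar(precursors$sequence[prec_idx])
    len <- pmin(len, plen)
    start <- 1L + floor(runif(n) * (plen - len + 1))
    tibble::tibble(
      sequence = substr(precursors$sequence[prec_idx], start, start + len - 1L),
      precursor = precursors$name[prec_idx],
      start = as.integer(start + precursors$offset[prec_idx] - 1L),
      end = as.integer(start + len - 1L + precursors$offset[prec_idx] - 1L))
  }

  seen <- character(0)
  draw_unique <- function(n, w) {
    got <- NULL
    while (is.null(got) || nrow(got) < n) {
      batch <- draw_batch(max(2L * n, 50L), w)
      batch <- batch[!duplicated(batch$sequence) & !(batch$sequence %in% seen), ]
      got <- rbind(got, batch)
      got <- got[!duplicated(got$sequence), ]
    }
    got <- got[seq_len(n), ]
    seen <<- c(seen, got$sequence)
    got
  }

  core_w <- matrix(colMeans(weights), nrow = 1,
                   dimnames = list(NULL, colnames(weights)))
  core <- draw_unique(n_core, core_w)
  core$samples <- rep(list(sort(samples$sample)), nrow(core))
  parts <- list(core)
  for (i in seq_len(k)) {
    n_extra <- samples$total[i] - n_core
    if (n_extra > 0) {
      extra <- draw_unique(n_extra, weights[i, , drop = FALSE])
      extra$samples <- rep(list(samples$sample[i]), nrow(extra))
      parts[[length(parts) + 1L]] <- extra
    }
  }
  out <- do.call(rbind, parts)
  out$modifications <- rep(list(character(0)), nrow(out))
  out <- out[order(out$sequence), ]
  attr(out, "sim_config") <- list(samples = samples, n_core = n_core,
                                  weights = weights, seed = seed)
  out
}

# discrete triangular distribution on lo..hi with the given mode
draw_triangular <- function(n, lo, hi, mode) {
  vals <- lo:hi
  peak <- pmin(pmax(mode, lo), hi)
  up <- ifelse(vals <= peak, vals - lo + 1, 0)
  down <- ifelse(vals >= peak, hi - vals + 1, 0)
  w <- pmin(ifelse(up > 0, up, Inf), ifelse(down > 0, down, Inf))
  w[!is.finite(w)] <- 0
  sample(vals, n, replace = TRUE, prob = w)
}

#' Simulate external predictor score tables
#'
#' Generates plausible bioactivity scores and per-target docking p-values
#' for a list of peptides, as a stand-in for the external predictors whose
#' outputs the screening cascade consumes. A configurable fraction of
#' peptides scores above the bioactivity threshold, and a fraction of
#' docking p-values falls below the significance cut-off.
#'
#' @param sequences Character vector of peptide sequences.
#' @param frac_active Fraction with bioactivity score above `threshold`
#'   (default 0.3, roughly the above-threshold rate seen in cheese
#'   peptidome screens).
#' @param frac_binding Fraction with docking p below `alpha`, per target
#'   (default 0.6).
#' @param threshold,alpha The screening cut-offs the fractions refer to.
#' @param seed Integer seed.
#' @return A score tibble with columns `sequence`, `ranker_score`,
#'   `p_dppiv`, `p_glucosidase`, `p_amylase`.
#' @export
#' @examples
#' simulate_scores(c("IPP", "LPPT"), seed = 7)
simulate_scores <- function(sequences, frac_active = 0.3, frac_binding = 0.6,
                            threshold = 0.5, alpha = 0.01, seed = 1L) {
  check_aa(sequences, "peptide")
  stopifnot(frac_active >= 0, frac_active <= 1,
            frac_binding >= 0, frac_binding <= 1)
  set.seed(as.integer(seed))
  n <- length(sequences)
  active <- runif(n) < frac_active
  score <- ifelse(active,
                  runif(n, threshold, 1),
                  runif(n, 0, threshold))
  draw_p <- function() {
    sig <- runif(n) < frac_binding
    ifelse(sig, 10^runif(n, -6, log10(alpha)), runif(n, alpha, 1))
  }
  tibble::tibble(sequence = sequences, ranker_score = score,
                 p_dppiv = draw_p(), p_glucosidase = draw_p(),
                 p_amylase = draw_p())
}

#' Simulate a dose-response inhibition curve
#'
#' Generates replicate percent-inhibition measurements on a concentration
#' grid under the log-linear model used by [fit_ic50()] (or its logistic
#' counterpart), with additive Gaussian noise per replicate. Mirrors the
#' design of plate-reader inhibition assays run in triplicate.
#'
#' @param ic50 True IC50 (in the units of `concentrations`).
#' @param slope Log-linear slope in percent per decade of concentration
#'   (default 40); for `model = "logistic"`, the Hill slope is
#'   `slope / 57.6` so both models share the same midpoint steepness.
#' @param concentrations Concentration grid; defaults to five points
#'   log-spaced over `ic50 * 10^(-0.8 .. 0.8)`.
#' @param noise_sd Gaussian noise standard deviation in percent
#'   (default 3, typical plate-reader triplicate scatter).
#' @param replicates Replicates per concentration (default 3).
#' @param model `"loglinear"` (default) or `"logistic"`.
#' @param analyte Label for the curve.
#' @param units Concentration units label.
#' @param seed Integer seed.
#' @return A dose-response tibble with columns `analyte`, `concentration`,
#'   `units`, `replicate`, `inhibition`.
#' @export
#' @examples
#' curve <- simulate_dose_response(ic50 = 2.74, noise_sd = 0, seed = 1)
#' fit_ic50(curve)$value  # 2.74 exactly
simulate_dose_response <- function(ic50, slope = 40, concentrations = NULL,
                                   noise_sd = 3, replicates = 3L,
                                   model = c("loglinear", "logistic"),
                                   analyte = "peptide", units = "mg/mL",
                                   seed = 1L) {
  model <- match.arg(model)
  stopifnot(ic50 > 0, replicates >= 1)
  concentrations <- concentrations %||% (ic50 * 10^seq(-0.8, 0.8, length.out = 5))
  stopifnot(all(concentrations > 0))
  set.seed(as.integer(seed))
  grid <- expand.grid(concentration = concentrations,
                      replicate = seq_len(replicates))
  mean_inh <- if (model == "loglinear") {
    50 + slope * (log10(grid$concentration) - log10(ic50))
  } else {
    100 / (1 + 10^((slope / 57.6) * (log10(ic50) - log10(grid$concentration))))
  }
  tibble::tibble(
    analyte = analyte,
    concentration = grid$concentration,
    units = units,
    replicate = grid$replicate,
    inhibition = mean_inh + rnorm(nrow(grid), 0, noise_sd)
  )
}

#' Write a complete synthetic demo dataset
#'
#' Emits, under `dir`, every input the pipeline consumes in the formats it
#' reads: the bundled mature casein FASTA and bioactivity reference, a
#' simulated peptidome table, a simulated predictor score table for its
#' peptides, and simulated dose-response curves.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed driving all three generators.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_demo_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    precursors = file.path(dir, "precursors.fasta"),
    peptides = file.path(dir, "peptides.tsv"),
    reference = file.path(dir, "bioactivity_reference.tsv"),
    scores = file.path(dir, "scores.tsv"),
    dose_response = file.path(dir, "dose_response.tsv")
  )
  precursors <- read_precursors(pepscreen_extdata("caseins_mature.fasta"))
  write_precursors(precursors, paths["precursors"])
  file.copy(pepscreen_extdata("bioactivity_reference.tsv"),
            paths["reference"], overwrite = TRUE)
  peps <- simulate_peptidome(precursors, seed = seed)
  write_peptide_table(peps, paths["peptides"])
  short <- unique(peps$sequence[nchar(peps$sequence) <= 10])
  scores <- simulate_scores(short, seed = seed + 1L)
  utils::write.table(scores, paths["scores"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  curves <- do.call(rbind, lapply(seq_len(6), function(i) {
    simulate_dose_response(ic50 = c(1.9, 2.7, 0.8, 3.5, 1.2, 2.2)[i],
                           analyte = paste0("extract", i), seed = seed + 1L + i)
  }))
  utils::write.table(curves, paths["dose_response"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
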