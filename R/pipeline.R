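#' Census of a peptidome: counts, incidence, Venn, bioactivity
#'
#' End-to-end reproduction of the descriptive stage of the workflow:
#' per-sample peptide counts, precursor incidence, the Venn partition of
#' peptides across samples, and -- when a bioactivity reference is given --
#' per-class and per-sample bioactive peptide counts. Rows failing
#' assignment validation are reported and dropped; the run continues with
#' the valid rows.
#'
#' @param peptides A peptide table tibble or a path to one.
#' @param precursors A precursor tibble or FASTA path; defaults to the
#'   bundled mature caseins.
#' @param reference Optional bioactivity reference tibble or TSV path.
#' @param sample_order Optional sample ordering for reports.
#' @return A list of class `census_report`: `per_sample` (sample,
#'   `n_peptides`, `n_bioactive`), `incidence`, `venn`, `common_all`
#'   (count and percent of peptides shared by every sample),
#'   `activity_counts`, `annotated`, `violations`.
#' @export
#' @examples
#' rep <- run_census(pepscreen_extdata("pr_bioactive_peptides.tsv"),
#'                   reference = pepscreen_extdata("bioactivity_reference.tsv"))
#' rep$per_sample
run_census <- function(peptides,
                       precursors = NULL,
                       reference = NULL,
                       sample_order = NULL) {
  if (is.character(peptides)) peptides <- read_peptide_table(peptides)
  precursors <- precursors %||% pepscreen_extdata("caseins_mature.fasta")
  if (is.character(precursors)) precursors <- read_precursors(precursors)
  if (is.character(reference)) reference <- read_bioactivity_reference(reference)

  violations <- validate_assignments(peptides, precursors)
  if (nrow(violations) > 0) {
    warning(nrow(violations), " assignment violation(s); offending rows ",
            "dropped from the census", call. = FALSE)
    peptides <- peptides[-violations$row, ]
  }
  sets <- peptide_sets(peptides, sample_order)
  per_sample <- tibble::tibble(sample = names(sets),
                               n_peptides = lengths(sets))
  n_total <- length(unique(peptides$sequence))
  venn <- if (length(sets) >= 2) venn_partition(sets) else NULL
  all_region <- if (!is.null(venn)) {
    venn$count[venn$n_samples == length(sets)]
  } else integer(0)
  n_common <- if (length(all_region) == 1) all_region else 0L
  common_all <- tibble::tibble(
    count = n_common, total = n_total,
    percent = if (n_total > 0) common_fraction(n_common, n_total) else NA_real_)
  incidence <- precursor_incidence(peptides, precursors$name, sample_order)

  annotated <- NULL
  activity_counts <- NULL
  if (!is.null(reference)) {
    annotated <- match_peptides(peptides, reference)
    per_sample$n_bioactive <- vapply(per_sample$sample, function(s) {
      count_common_to_all(annotated, s)
    }, integer(1), USE.NAMES = FALSE)
    acts <- sort(unique(unlist(annotated$activities)))
    activity_counts <- tibble::tibble(
      activity = acts,
      count = vapply(acts, function(a) count_by_activity(annotated, a),
                     integer(1), USE.NAMES = FALSE))
  }
  structure(list(per_sample = per_sample, incidence = incidence, venn = venn,
                 common_all = common_all, activity_counts = activity_counts,
                 annotated = annotated, violations = violations,
                 n_total = n_total),
            class = "census_report")
}

#' @export
print.census_report <- function(x, ...) {
  cat("Peptidome census:", x$n_total, "distinct peptides across",
      nrow(x$per_sample), "samples\n")
  print(x$per_sample)
  cat("\nShared by all samples:", x$common_all$count,
      sprintf("(%.1f%%)\n", x$common_all$percent))
  if (!is.null(x$activity_counts)) {
    cat("\nBioactive peptides by class:\n")
    print(x$activity_counts)
  }
  if (nrow(x$violations) > 0) {
    cat("\n", nrow(x$violations), "assignment violation(s) dropped\n")
  }
  invisible(x)
}

#' Full candidate-selection screen
#'
#' Runs the complete selection cascade per target, with an auditable
#' per-row trace: score / length / docking filters ([filter_cascade()]),
#' the target's structure-activity consensus ([sar_verdict()]), removal of
#' peptides already reported with the same activity in the bioactivity
#' reference ("known"), and the gastro-intestinal stability filter
#' ([classify_stability()]). Final candidates are the retained, consensus-
#' positive, novel, stable peptides. Targets without a structure-activity
#' model (alpha-amylase) yield no candidates: selection there stops at the
#' docking stage.
#'
#' @param scores Score tibble ([read_screening_scores()]) or TSV path.
#' @param config A [screening_config()].
#' @param reference Optional bioactivity reference (tibble or path) used
#'   to flag known peptides.
#' @param rules Cleavage rules for the stability filter; defaults to
#'   [gi_panel()].
#' @param modified Character vector of sequences carrying
#'   post-translational modifications, excluded up front.
#' @return A list of class `screen_report`: `trace` (one row per
#'   sequence x target with every filter column) and `candidates` (named
#'   list of final candidate sequences per target).
#' @export
#' @examples
#' scores <- simulate_scores(c("IPP", "LPPT", "FALPQ"), frac_active = 1,
#'                           frac_binding = 1, seed = 1)
#' run_screen(scores, screening_config(targets = "DPP-IV"))$candidates
run_screen <- function(scores, config = screening_config(),
                       reference = NULL, rules = gi_panel(),
                       modified = character(0)) {
  if (is.character(scores)) scores <- read_screening_scores(scores)
  if (is.character(reference)) reference <- read_bioactivity_reference(reference)
  trace <- filter_cascade(scores, config, modified)
  stability <- classify_stability(unique(scores$sequence), rules)
  trace$pass_sar <- NA
  trace$known <- FALSE
  trace$stable <- stability$stable[match(trace$sequence, stability$sequence)]
  for (target in config$targets) {
    idx <- trace$target == target
    sar <- sar_verdict(trace$sequence[idx], target, config$p_window)
    trace$pass_sar[idx] <- sar$pass
    if (!is.null(reference)) {
      known_seqs <- reference$sequence[reference$activity == target_activity(target)]
      trace$known[idx] <- trace$sequence[idx] %in% known_seqs
    }
  }
  trace$candidate <- trace$retained &
    !is.na(trace$pass_sar) & trace$pass_sar &
    !trace$known & trace$stable
  candidates <- lapply(config$targets, function(t) {
    trace$sequence[trace$target == t & trace$candidate]
  })
  names(candidates) <- config$targets
  structure(list(trace = trace, candidates = candidates, config = config),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  for (t in names(x$candidates)) {
    cand <- x$candidates[[t]]
    cat(t, ": ", if (length(cand) == 0) "(no candidates)" else
      paste(cand, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' IC50 and serving-size report from dose-response data
#'
#' Fits one IC50 per analyte ([fit_ic50()]) and reports them in an assay
#' table mirroring the usual presentation, with censored fits flagged as
#' `"> c_max"` rather than failing. When `peptide_content` is given and
#' the curves are in mg/mL, a serving-size estimate ([estimate_serving()])
#' is added per analyte.
#'
#' @param curves Dose-response tibble ([read_dose_response()]) or TSV
#'   path; column `analyte` separates the curves.
#' @param peptide_content Optional peptide content (mg per g cheese) for
#'   the serving estimate.
#' @param serving_mass,dilution_factor Serving model parameters (defaults
#'   50 g, 10-fold).
#' @param method Passed to [fit_ic50()].
#' @return A tibble with one row per analyte: `analyte`, `ic50`, `se`,
#'   `slope`, `r_squared`, `censored`, `label`, `units`, and `serving_g`
#'   when `peptide_content` was supplied.
#' @export
run_assay <- function(curves, peptide_content = NULL, serving_mass = 50,
                      dilution_factor = 10,
                      method = c("loglinear", "logistic")) {
  method <- match.arg(method)
  if (is.character(curves)) curves <- read_dose_response(curves)
  if (!"analyte" %in% names(curves)) curves$analyte <- "analyte"
  rows <- lapply(split(curves, curves$analyte), function(cc) {
    fit <- fit_ic50(cc, method = method)
    tibble::tibble(analyte = unique(cc$analyte)[1], ic50 = fit$value,
                   se = fit$se, slope = fit$slope,
                   r_squared = fit$r_squared, censored = fit$censored,
                   label = fit$label, units = fit$units)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(peptide_content)) {
    out$serving_g <- NA_real_
    ok <- !out$censored & !is.na(out$ic50)
    if (any(ok)) {
      out$serving_g[ok] <- estimate_serving(out$ic50[ok], peptide_content,
                                            serving_mass, dilution_factor)
    }
  }
  out
}
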