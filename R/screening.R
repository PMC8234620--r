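#' Screening configuration
#'
#' Thresholds for the in silico candidate-selection cascade. Defaults
#' follow common practice for the external predictors whose outputs are
#' consumed here: a general bioactivity score is kept when strictly above
#' 0.5; peptides longer than 10 residues are dropped (the docking
#' predictor's maximum input length); docking p-values must be strictly
#' below 0.01.
#'
#' @param score_threshold Bioactivity score cut-off in `[0, 1]`; peptides
#'   with score strictly greater are retained. Default 0.5.
#' @param max_length Maximum peptide length in residues. Default 10.
#' @param docking_alpha Docking significance level in `(0, 1)`; retained
#'   when `p < docking_alpha`. Default 0.01.
#' @param targets Enzyme targets to screen. Default all three.
#' @param p_window Window (in residues from the C-terminus) used by the
#'   alpha-glucosidase "proline close to the C-terminal end" feature.
#'   Default 3.
#' @return A list of class `screening_config`.
#' @export
#' @examples
#' screening_config()
screening_config <- function(score_threshold = 0.5, max_length = 10L,
                             docking_alpha = 0.01,
                             targets = c("DPP-IV", "alpha-glucosidase",
                                         "alpha-amylase"),
                             p_window = 3L) {
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            max_length >= 1, docking_alpha > 0, docking_alpha < 1,
            p_window >= 1)
  structure(list(score_threshold = score_threshold,
                 max_length = as.integer(max_length),
                 docking_alpha = docking_alpha,
                 targets = targets,
                 p_window = as.integer(p_window)),
            class = "screening_config")
}

# docking p-value column for each target
target_p_column <- function(target) {
  switch(target,
         "DPP-IV" = "p_dppiv",
         "alpha-glucosidase" = "p_glucosidase",
         "alpha-amylase" = "p_amylase",
         stop("unknown screening target: ", target, call. = FALSE))
}

# reference activity class corresponding to a screening target
target_activity <- function(target) {
  switch(target,
         "DPP-IV" = "DPP-IV-inhibition",
         "alpha-glucosidase" = "alpha-glucosidase-inhibition",
         "alpha-amylase" = "alpha-amylase-inhibition",
         stop("unknown screening target: ", target, call. = FALSE))
}

#' Read an external predictor score table
#'
#' Scores are inputs, not computed here: `ranker_score` is a general
#' bioactivity probability in `[0, 1]` and `p_dppiv` / `p_glucosidase` /
#' `p_amylase` are docking binding p-values in `(0, 1]` for the three
#' enzyme targets.
#'
#' @param path Path to a TSV with columns `sequence`, `ranker_score` and
#'   one `p_*` column per target.
#' @return A tibble.
#' @export
read_screening_scores <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sequence", "ranker_score")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("score table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_aa(raw$sequence, "scored sequence")
  if (any(raw$ranker_score < 0 | raw$ranker_score > 1, na.rm = TRUE)) {
    stop("ranker_score must lie in [0, 1]", call. = FALSE)
  }
  tibble::as_tibble(raw)
}

#' Score, length and docking filter cascade
#'
#' Applies the first three stages of the candidate-selection cascade to an
#' external predictor score table, independently per target: sequences
#' carrying post-translational modifications are excluded up front, then a
#' sequence is retained when its bioactivity score is strictly above the
#' threshold, its length is at most `max_length`, and its docking p-value
#' for the target is strictly below `docking_alpha`. Input order is
#' preserved. A sequence with a missing docking p-value for a requested
#' target is excluded from that target with a warning.
#'
#' @param scores Score tibble ([read_screening_scores()]).
#' @param config A [screening_config()].
#' @param modified Character vector of sequences to exclude (peptides
#'   observed with post-translational modifications).
#' @return A tibble with one row per (sequence, target):
#'   `sequence`, `target`, `excluded_modified`, `pass_score`,
#'   `pass_length`, `pass_docking`, `retained`.
#' @export
#' @examples
#' scores <- tibble::tibble(sequence = c("IPP", "GGG"),
#'                          ranker_score = c(0.9, 0.2),
#'                          p_dppiv = c(1e-4, 0.5))
#' filter_cascade(scores, screening_config(targets = "DPP-IV"))
filter_cascade <- function(scores, config = screening_config(),
                           modified = character(0)) {
  stopifnot(inherits(config, "screening_config"))
  out <- list()
  for (target in config$targets) {
    pcol <- target_p_column(target)
    p <- if (pcol %in% names(scores)) scores[[pcol]] else rep(NA_real_, nrow(scores))
    if (anyNA(p) && nrow(scores) > 0) {
      warning(sum(is.na(p)), " sequence(s) lack a docking p-value for ",
              target, " and are excluded from that target", call. = FALSE)
    }
    excluded_modified <- scores$sequence %in% modified
    pass_score <- !is.na(scores$ranker_score) &
      scores$ranker_score > config$score_threshold
    pass_length <- nchar(scores$sequence) <= config$max_length
    pass_docking <- !is.na(p) & p < config$docking_alpha
    out[[target]] <- tibble::tibble(
      sequence = scores$sequence,
      target = target,
      excluded_modified = excluded_modified,
      pass_score = pass_score,
      pass_length = pass_length,
      pass_docking = pass_docking,
      retained = !excluded_modified & pass_score & pass_length & pass_docking
    )
  }
  do.call(rbind, out)
}

#' DPP-IV inhibitor consensus rule
#'
#' Structure-activity consensus for DPP-IV-inhibitory peptides: a
#' branched-chain / bulky hydrophobic residue (I, L, A, M, F, W) at the
#' N-terminus and P or A in second position. A peptide shorter than two
#' residues fails with a reason.
#'
#' @param sequences Character vector of peptide sequences.
#' @return A tibble with columns `sequence`, `target`, `pass`,
#'   `features_met` (list of named features, here `n_terminal_bulky` and
#'   `second_pro_ala`), and `reason` for failures.
#' @export
#' @examples
#' dppiv_consensus(c("APFPE", "GTQY"))$pass
dppiv_consensus <- function(sequences) {
  check_aa(sequences, "peptide")
  r1 <- substr(sequences, 1, 1)
  r2 <- substr(sequences, 2, 2)
  too_short <- nchar(sequences) < 2
  f1 <- r1 %in% c("I", "L", "A", "M", "F", "W")
  f2 <- !too_short & r2 %in% c("P", "A")
  pass <- !too_short & f1 & f2
  tibble::tibble(
    sequence = sequences,
    target = "DPP-IV",
    pass = pass,
    features_met = Map(function(a, b) {
      c("n_terminal_bulky", "second_pro_ala")[c(a, b)]
    }, f1, f2),
    reason = ifelse(too_short, "length < 2",
                    ifelse(pass, NA_character_, "consensus not met"))
  )
}

#' Alpha-glucosidase inhibitor feature rule
#'
#' Structure-activity features reported for potent alpha-glucosidase
#' inhibitory peptides: (F1) a hydroxyl-containing (S, T, Y) or basic
#' (K, R) residue at the N-terminus; (F2) a hydrophobic residue (M, A, F)
#' at the C-terminus; (F3) a proline close to the C-terminal end,
#' operationalised as within the last `p_window` residues. A peptide
#' passes when at least two of the three features hold.
#'
#' @param sequences Character vector of peptide sequences.
#' @param p_window Size of the C-terminal window scanned for proline
#'   (default 3, the loosest reading consistent with the calibration
#'   peptides).
#' @return A tibble with columns `sequence`, `target`, `f1_n_terminal`,
#'   `f2_c_terminal`, `f3_proline`, `n_features`, `pass`, `features_met`.
#' @export
#' @examples
#' glucosidase_features(c("KIHPF", "PPF", "GGG"))$pass
glucosidase_features <- function(sequences, p_window = 3L) {
  check_aa(sequences, "peptide")
  stopifnot(p_window >= 1)
  n <- nchar(sequences)
  f1 <- substr(sequences, 1, 1) %in% c("S", "T", "Y", "K", "R")
  f2 <- substr(sequences, n, n) %in% c("M", "A", "F")
  tail_start <- pmax(1L, n - as.integer(p_window) + 1L)
  f3 <- grepl("P", substr(sequences, tail_start, n), fixed = TRUE)
  n_features <- f1 + f2 + f3
  tibble::tibble(
    sequence = sequences,
    target = "alpha-glucosidase",
    f1_n_terminal = f1,
    f2_c_terminal = f2,
    f3_proline = f3,
    n_features = as.integer(n_features),
    pass = n_features >= 2,
    features_met = Map(function(a, b, c) {
      c("n_terminal_hydroxyl_or_basic", "c_terminal_hydrophobic",
        "proline_near_c_terminus")[c(a, b, c)]
    }, f1, f2, f3)
  )
}

#' Structure-activity verdict for a target
#'
#' Dispatches to the consensus rule for the given target. Targets without
#' a published structure-activity model (alpha-amylase) return `NA`
#' verdicts: no candidate can be selected on structural grounds.
#'
#' @param sequences Character vector of peptide sequences.
#' @param target One of `"DPP-IV"`, `"alpha-glucosidase"`,
#'   `"alpha-amylase"`.
#' @param p_window Passed to [glucosidase_features()].
#' @return A tibble with at least `sequence`, `target`, `pass`.
#' @export
sar_verdict <- function(sequences, target, p_window = 3L) {
  switch(target,
         "DPP-IV" = dppiv_consensus(sequences),
         "alpha-glucosidase" = glucosidase_features(sequences, p_window),
         "alpha-amylase" = tibble::tibble(
           sequence = sequences, target = "alpha-amylase", pass = NA,
           features_met = rep(list(character(0)), length(sequences)),
           reason = "no structure-activity model available"),
         stop("unknown screening target: ", target, call. = FALSE))
}
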