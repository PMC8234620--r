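#' Read a bioactive-peptide reference table
#'
#' The reference emulates database records of previously demonstrated
#' bioactive peptides (in the style of BIOPEP and the Milk Bioactive
#' Peptides Database): one row per (sequence, activity) pair, with an
#' optional reported potency. Columns: `sequence`, `activity`,
#' `potency_value`, `potency_units`, `source`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per (sequence, activity) pair.
#' @export
#' @examples
#' ref <- read_bioactivity_reference(pepscreen_extdata("bioactivity_reference.tsv"))
#' table(ref$activity)
read_bioactivity_reference <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("sequence", "activity")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("reference table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_aa(raw$sequence, "reference sequence")
  if (anyDuplicated(paste(raw$sequence, raw$activity))) {
    stop("duplicate (sequence, activity) pairs in reference", call. = FALSE)
  }
  tibble::tibble(
    sequence = raw$sequence,
    activity = raw$activity,
    potency_value = if ("potency_value" %in% names(raw))
      suppressWarnings(as.numeric(raw$potency_value)) else NA_real_,
    potency_units = if ("potency_units" %in% names(raw))
      as.character(raw$potency_units) else NA_character_,
    source = if ("source" %in% names(raw)) as.character(raw$source)
             else NA_character_
  )
}

#' Annotate peptides against the bioactivity reference
#'
#' A peptide is annotated if and only if its full sequence is identical to
#' a reference sequence (100\% identity over the full length; no substring
#' or homology matching). All matching activity classes are attached.
#' Unmatched peptides are excluded from the output.
#'
#' @param peptides A peptide table tibble ([read_peptide_table()]), or a
#'   plain character vector of sequences.
#' @param reference A reference tibble ([read_bioactivity_reference()]).
#' @return A tibble sorted by sequence with columns `sequence`,
#'   `activities` (list of class labels), `samples` (list; union over the
#'   peptide table's records, empty for character input), and `potencies`
#'   (list of per-activity potency tibbles).
#' @export
#' @examples
#' ref <- read_bioactivity_reference(pepscreen_extdata("bioactivity_reference.tsv"))
#' match_peptides(c("IPP", "QQQQ"), ref)$activities
match_peptides <- function(peptides, reference) {
  if (nrow(reference) == 0) stop("reference is empty", call. = FALSE)
  if (is.character(peptides)) {
    if (length(peptides) > 0) check_aa(peptides, "peptide")
    seqs <- sort(unique(peptides))
    samples <- setNames(rep(list(character(0)), length(seqs)), seqs)
  } else {
    seqs <- sort(unique(peptides$sequence))
    samples <- lapply(seqs, function(s) {
      sort(unique(unlist(peptides$samples[peptides$sequence == s])))
    })
    names(samples) <- seqs
  }
  hit <- seqs[seqs %in% reference$sequence]
  rows <- lapply(hit, function(s) {
    sub <- reference[reference$sequence == s, ]
    tibble::tibble(
      sequence = s,
      activities = list(sort(unique(sub$activity))),
      samples = list(samples[[s]]),
      potencies = list(tibble::tibble(activity = sub$activity,
                                      value = sub$potency_value,
                                      units = sub$potency_units))
    )
  })
  if (length(rows) == 0) {
    return(tibble::tibble(sequence = character(), activities = list(),
                          samples = list(), potencies = list()))
  }
  do.call(rbind, rows)
}

#' Count annotated peptides carrying an activity class
#'
#' Counts distinct sequences whose activity set contains `activity`. An
#' activity label absent from the whole annotation yields 0 with a warning
#' (a likely misspelling).
#'
#' @param annotated Output of [match_peptides()].
#' @param activity A single activity class label, e.g. `"ACE-inhibition"`.
#' @return Integer count.
#' @export
count_by_activity <- function(annotated, activity) {
  stopifnot(length(activity) == 1)
  all_act <- unique(unlist(annotated$activities))
  if (!activity %in% all_act) {
    warning("activity label '", activity, "' not present in annotation",
            call. = FALSE)
    return(0L)
  }
  sum(vapply(annotated$activities, function(a) activity %in% a, logical(1)))
}

#' Count peptides common to a set of samples
#'
#' Counts distinct annotated sequences observed in every listed sample.
#'
#' @param annotated Output of [match_peptides()] (or any tibble with
#'   `sequence` and a `samples` list-column).
#' @param sample_ids Non-empty character vector of sample identifiers.
#' @return Integer count.
#' @export
count_common_to_all <- function(annotated, sample_ids) {
  if (length(sample_ids) == 0) stop("sample_ids must be non-empty", call. = FALSE)
  sum(vapply(annotated$samples, function(s) all(sample_ids %in% s), logical(1)))
}
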