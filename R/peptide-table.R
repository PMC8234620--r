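#' Read a peptide identification table
#'
#' The table is TSV with one row per (peptide sequence, precursor
#' assignment); peptides mapping to several precursors (e.g. LPQ, found in
#' all three caseins) span several rows that share the sequence. Required
#' columns: `sequence`, `precursor`, `start`, `end`, `samples`
#' (semicolon-separated sample identifiers). Optional column:
#' `modifications` (semicolon-separated `position:kind` tokens, `kind` in
#' `oxidation`/`phosphorylation`).
#'
#' @param path Path to a TSV file.
#' @return A tibble with parsed columns; `samples` and `modifications`
#'   become list-columns of character vectors (sorted, deduplicated, so
#'   that write-then-read is an identity).
#' @export
#' @examples
#' peps <- read_peptide_table(pepscreen_extdata("pr_bioactive_peptides.tsv"))
#' length(unique(peps$sequence))  # 49 distinct bioactive sequences
read_peptide_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = TRUE)
  required <- c("sequence", "precursor", "start", "end", "samples")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("peptide table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) return(empty_peptide_table())
  check_aa(raw$sequence, "peptide sequence")
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop("malformed coordinates in ", path, " at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sequence = raw$sequence,
    precursor = raw$precursor,
    start = start,
    end = end,
    samples = split_set(raw$samples),
    modifications = if ("modifications" %in% names(raw)) split_set(raw$modifications)
                    else rep(list(character(0)), nrow(raw))
  )
  out
}

empty_peptide_table <- function() {
  tibble::tibble(sequence = character(), precursor = character(),
                 start = integer(), end = integer(),
                 samples = list(), modifications = list())
}

#' Write a peptide table to TSV
#'
#' Inverse of [read_peptide_table()]; list-columns are serialised as
#' semicolon-separated fields. Round-tripping a table through
#' `write_peptide_table()` and [read_peptide_table()] is lossless.
#'
#' @param peptides A peptide table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(peptides, path) {
  flat <- data.frame(
    sequence = peptides$sequence,
    precursor = peptides$precursor,
    start = peptides$start,
    end = peptides$end,
    samples = join_set(peptides$samples),
    modifications = join_set(peptides$modifications %||% rep(list(character(0)), nrow(peptides))),
    stringsAsFactors = FALSE
  )
  utils::write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-sample peptide sets
#'
#' Expands the `samples` list-column into named sets of distinct peptide
#' sequences, one per sample, ordered by `sample_order` when given.
#'
#' @param peptides A peptide table tibble.
#' @param sample_order Optional character vector fixing the sample order
#'   (e.g. by ripening months); defaults to sorted order of the observed ids.
#' @return A named list of character vectors of sequences.
#' @export
#' @examples
#' peps <- read_peptide_table(pepscreen_extdata("pr_bioactive_peptides.tsv"))
#' lengths(peptide_sets(peps))  # 30, 35, 41, 39 for PR12..PR30
peptide_sets <- function(peptides, sample_order = NULL) {
  pairs <- unique(data.frame(
    sequence = rep(peptides$sequence, lengths(peptides$samples)),
    sample = unlist(peptides$samples),
    stringsAsFactors = FALSE
  ))
  ids <- sample_order %||% sort(unique(pairs$sample))
  sets <- lapply(ids, function(s) sort(unique(pairs$sequence[pairs$sample == s])))
  names(sets) <- ids
  sets
}

#' Sequences carrying post-translational modifications
#'
#' Peptides observed with oxidation or phosphorylation are retained in
#' census statistics but excluded from the screening cascade; this helper
#' extracts the set to exclude.
#'
#' @param peptides A peptide table tibble.
#' @return Character vector of distinct modified sequences.
#' @export
modified_sequences <- function(peptides) {
  if (!"modifications" %in% names(peptides)) return(character(0))
  sort(unique(peptides$sequence[lengths(peptides$modifications) > 0]))
}
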