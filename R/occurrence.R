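#' Venn partition of peptide sets across samples
#'
#' Partitions the union of all observed sequences into disjoint Venn
#' regions, one per non-empty combination of samples. Region counts sum to
#' the cardinality of the union.
#'
#' @param sets Either a named list of character vectors (one set of
#'   sequences per sample) or a peptide table tibble, in which case
#'   [peptide_sets()] is applied first.
#' @param sample_order Optional sample ordering for region labels.
#' @return A tibble with columns `region` (semicolon-joined sample ids, in
#'   `sample_order`), `n_samples`, `count`, and `members` (list-column of
#'   sequences). Only non-empty regions are returned, sorted by decreasing
#'   `n_samples` then region label.
#' @export
#' @examples
#' venn_partition(list(A = c("IPP", "VPP"), B = c("VPP", "LPQ")))
venn_partition <- function(sets, sample_order = NULL) {
  if (!is.list(sets)) stop("sets must be a list or peptide table", call. = FALSE)
  if (tibble::is_tibble(sets) || is.data.frame(sets)) {
    sets <- peptide_sets(sets, sample_order)
  }
  if (length(sets) < 2) stop("need at least two samples", call. = FALSE)
  ids <- sample_order %||% names(sets)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids))) {
    stop("sets must have unique non-empty names", call. = FALSE)
  }
  sets <- sets[ids]
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0) {
    return(tibble::tibble(region = character(), n_samples = integer(),
                          count = integer(), members = list()))
  }
  membership <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  membership <- matrix(membership, nrow = length(universe),
                       dimnames = list(universe, ids))
  profile <- apply(membership, 1, function(m) paste(ids[m], collapse = ";"))
  regions <- split(universe, profile)
  out <- tibble::tibble(
    region = names(regions),
    n_samples = unname(lengths(strsplit(names(regions), ";", fixed = TRUE))),
    count = unname(lengths(regions)),
    members = unname(lapply(regions, sort))
  )
  out[order(-out$n_samples, out$region), ]
}

#' Shared-core percentage
#'
#' The percentage of the total peptidome common to all samples, rounded
#' half-up to one decimal as conventionally printed (e.g. 228 of 415
#' peptides shared across four ripening times is 54.9\%).
#'
#' @param common_count Number of shared peptides.
#' @param total_count Total distinct peptides (> 0).
#' @return Percentage with one decimal.
#' @export
#' @examples
#' common_fraction(228, 415)  # 54.9
common_fraction <- function(common_count, total_count) {
  if (any(total_count <= 0)) stop("total_count must be positive", call. = FALSE)
  if (any(common_count > total_count) || any(common_count < 0)) {
    stop("common_count must be in [0, total_count]", call. = FALSE)
  }
  round_half_up(100 * common_count / total_count, 1)
}

#' Precursor incidence per sample
#'
#' For each sample, counts the distinct peptides with at least one
#' assignment to each precursor protein and expresses the count as a
#' percentage of the sample's peptidome size (half-up, one decimal). A
#' peptide assigned to several precursors contributes to each of their
#' counts (so, in pathological inputs, percentages can sum above 100).
#'
#' @param peptides A peptide table tibble.
#' @param precursor_names Optional precursor names to report (defaults to
#'   all observed); order is preserved in the output.
#' @param sample_order Optional sample ordering.
#' @return A tibble with columns `sample`, `precursor`, `count`,
#'   `peptidome_size`, `percent`.
#' @export
#' @examples
#' peps <- read_peptide_table(pepscreen_extdata("pr_bioactive_peptides.tsv"))
#' precursor_incidence(peps)
precursor_incidence <- function(peptides, precursor_names = NULL,
                                sample_order = NULL) {
  sets <- peptide_sets(peptides, sample_order)
  precs <- precursor_names %||% unique(peptides$precursor)
  rows <- list()
  for (s in names(sets)) {
    size <- length(sets[[s]])
    for (p in precs) {
      on_p <- unique(peptides$sequence[peptides$precursor == p])
      count <- sum(sets[[s]] %in% on_p)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = s, precursor = p, count = count, peptidome_size = size,
        percent = if (size > 0) round_half_up(100 * count / size, 1) else NA_real_)
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(sample = character(), precursor = character(),
                          count = integer(), peptidome_size = integer(),
                          percent = numeric()))
  }
  do.call(rbind, rows)
}
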