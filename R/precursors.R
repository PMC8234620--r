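#' Read precursor proteins from a FASTA file
#'
#' Precursors are mature chains (signal peptide removed); fragment
#' coordinates throughout the package are 1-based inclusive on these chains.
#' The FASTA description line may carry `key=value` tokens; `offset=<int>`
#' sets the coordinate of the first residue (default 1), so that sources
#' numbering on the unprocessed pre-protein can still be represented.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `name`, `sequence`, `offset`, and
#'   `description`.
#' @export
#' @examples
#' read_precursors(pepscreen_extdata("caseins_mature.fasta"))
read_precursors <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("no FASTA records in ", path, call. = FALSE)
  header <- names(set)
  name <- sub("\\s.*$", "", header)
  desc <- sub("^\\S+\\s*", "", header)
  offset <- vapply(desc, function(d) {
    m <- regmatches(d, regexec("offset=(\\d+)", d))[[1]]
    if (length(m) == 2) as.integer(m[2]) else 1L
  }, integer(1), USE.NAMES = FALSE)
  seqs <- toupper(as.character(set))
  check_aa(seqs, "precursor sequence")
  if (anyDuplicated(name)) {
    stop("duplicate precursor names in ", path, call. = FALSE)
  }
  if (any(offset < 1)) stop("numbering offset must be >= 1", call. = FALSE)
  tibble::tibble(name = name, sequence = unname(seqs), offset = offset,
                 description = unname(desc))
}

#' Write precursor proteins to FASTA
#'
#' @param precursors Tibble as returned by [read_precursors()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_precursors <- function(precursors, path) {
  set <- Biostrings::AAStringSet(setNames(precursors$sequence, precursors$name))
  names(set) <- paste0(precursors$name, " offset=", precursors$offset)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Locate a peptide within precursor proteins
#'
#' Finds every (possibly overlapping) occurrence of `peptide` in each
#' precursor, reported in the precursor's own numbering (its `offset` plus
#' the 0-based match position). This reproduces the `f(start-end)` fragment
#' notation used for casein-derived peptides, e.g. IPP at f(74-76) of mature
#' beta-casein.
#'
#' @param peptide A single amino-acid sequence.
#' @param precursors A precursor tibble ([read_precursors()]), or a plain
#'   named character vector of sequences (offset 1).
#' @return A tibble with columns `precursor`, `start`, `end`, one row per
#'   occurrence, sorted by precursor then ascending start. Zero rows when
#'   the peptide does not occur.
#' @export
#' @examples
#' caseins <- read_precursors(pepscreen_extdata("caseins_mature.fasta"))
#' locate_fragment("IPP", caseins)
locate_fragment <- function(peptide, precursors) {
  check_aa(peptide, "peptide")
  stopifnot(length(peptide) == 1)
  if (is.character(precursors)) {
    precursors <- tibble::tibble(
      name = names(precursors) %||% paste0("precursor", seq_along(precursors)),
      sequence = unname(precursors), offset = 1L)
  }
  check_aa(precursors$sequence, "precursor sequence")
  out <- lapply(seq_len(nrow(precursors)), function(i) {
    hits <- Biostrings::matchPattern(peptide,
                                     Biostrings::AAString(precursors$sequence[i]))
    if (length(hits) == 0) return(NULL)
    off <- precursors$offset[i] - 1L
    tibble::tibble(precursor = precursors$name[i],
                   start = Biostrings::start(hits) + off,
                   end = Biostrings::end(hits) + off)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(tibble::tibble(precursor = character(), start = integer(),
                          end = integer()))
  }
  out[order(out$precursor, out$start), ]
}

#' Validate fragment assignments against precursor sequences
#'
#' Checks each row of a peptide table: the named precursor exists, the span
#' length equals the peptide length, and the precursor substring at
#' `[start, end]` (in the precursor's numbering) equals the peptide
#' sequence. Problems are collected, not thrown, so a whole identification
#' table can be audited in one pass.
#'
#' @param peptides A peptide table ([read_peptide_table()]): one row per
#'   (sequence, assignment) with columns `sequence`, `precursor`, `start`,
#'   `end`.
#' @param precursors A precursor tibble ([read_precursors()]).
#' @return A tibble of violations with columns `row`, `sequence`,
#'   `precursor`, `problem`; zero rows when every assignment is valid.
#' @export
#' @examples
#' caseins <- read_precursors(pepscreen_extdata("caseins_mature.fasta"))
#' peps <- read_peptide_table(pepscreen_extdata("pr_bioactive_peptides.tsv"))
#' validate_assignments(peps, caseins)
validate_assignments <- function(peptides, precursors) {
  viol <- list()
  note <- function(i, seq, prec, problem) {
    tibble::tibble(row = i, sequence = seq, precursor = prec, problem = problem)
  }
  for (i in seq_len(nrow(peptides))) {
    seq <- peptides$sequence[i]
    prec <- peptides$precursor[i]
    st <- peptides$start[i]
    en <- peptides$end[i]
    j <- match(prec, precursors$name)
    if (is.na(j)) {
      viol[[length(viol) + 1L]] <- note(i, seq, prec, "unknown precursor")
      next
    }
    if (is.na(st) || is.na(en) || st > en) {
      viol[[length(viol) + 1L]] <- note(i, seq, prec, "invalid coordinates")
      next
    }
    if (en - st + 1L != nchar(seq)) {
      viol[[length(viol) + 1L]] <- note(
        i, seq, prec,
        sprintf("span length %d != peptide length %d", en - st + 1L, nchar(seq)))
      next
    }
    off <- precursors$offset[j] - 1L
    lo <- st - off
    hi <- en - off
    if (lo < 1L || hi > nchar(precursors$sequence[j])) {
      viol[[length(viol) + 1L]] <- note(i, seq, prec, "coordinates outside precursor")
      next
    }
    found <- substr(precursors$sequence[j], lo, hi)
    if (found != seq) {
      viol[[length(viol) + 1L]] <- note(
        i, seq, prec,
        sprintf("precursor residues %d-%d are %s, not %s", st, en, found, seq))
    }
  }
  if (length(viol) == 0) {
    return(tibble::tibble(row = integer(), sequence = character(),
                          precursor = character(), problem = character()))
  }
  do.call(rbind, viol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
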