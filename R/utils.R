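#' Canonical amino-acid alphabet
#'
#' The twenty one-letter codes accepted throughout the package. Sequences are
#' taken as printed by the identification software: isobaric I/L are not
#' disambiguated, and non-canonical codes (B, Z, X, U, O) are rejected.
#'
#' @return A character vector of 20 single letters.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Validate amino-acid sequences
#'
#' Checks that every sequence is a non-empty uppercase string over the
#' canonical 20-letter alphabet.
#'
#' @param x Character vector of peptide or protein sequences.
#' @param what Label used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error naming the first
#'   offending sequence.
#' @export
#' @examples
#' check_aa("IPP")
check_aa <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) == 0) {
    stop(what, " must be a non-empty character vector", call. = FALSE)
  }
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x) | is.na(x)
  if (any(bad)) {
    stop(what, " contains invalid residues or is empty: ",
         paste(utils::head(x[bad], 3), collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds halves to even; the printed percentages and
#' serving sizes reproduced by this package use conventional half-up
#' rounding (0.5 rounds away from zero), so that is exposed here.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)        # 1, where round(0.5) == 0
#' round_half_up(54.94, 1)   # 54.9
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Path to a bundled example data file
#'
#' @param file Name of a file under the package's `extdata` directory;
#'   if `NULL`, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
#' @examples
#' pepscreen_extdata()
#' pepscreen_extdata("caseins_mature.fasta")
pepscreen_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "pepscreen")))
  }
  path <- system.file("extdata", file, package = "pepscreen")
  if (!nzchar(path)) stop("no bundled file named '", file, "'", call. = FALSE)
  path
}

# split a ";"-separated field into a sorted character set; "" -> character(0)
split_set <- function(x) {
  lapply(strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE),
         function(v) sort(unique(v[nzchar(v)])))
}

join_set <- function(x) {
  vapply(x, function(v) paste(sort(unique(v)), collapse = ";"), character(1))
}
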