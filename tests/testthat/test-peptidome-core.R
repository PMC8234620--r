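test_that("locate_fragment reproduces casein fragment coordinates", {
  caseins <- fixture_caseins()
  ipp <- locate_fragment("IPP", caseins)
  expect_equal(ipp$precursor, "beta-casein")
  expect_equal(c(ipp$start, ipp$end), c(74L, 76L))
  vpp <- locate_fragment("VPP", caseins)
  expect_equal(c(vpp$start, vpp$end), c(84L, 86L))
  expect_equal(nrow(locate_fragment("WWWW", caseins)), 0L)
  # multi-precursor peptide: LPQ occurs in all three caseins
  lpq <- locate_fragment("LPQ", caseins)
  expect_setequal(lpq$precursor,
                  c("beta-casein", "alphaS1-casein", "alphaS2-casein"))
  expect_error(locate_fragment("IP2", caseins), "invalid")
})

test_that("locate_fragment finds all overlapping occurrences and honours offsets", {
  # brute-force occurrence scan as the independent oracle
  brute <- function(pep, seq) {
    n <- nchar(seq) - nchar(pep) + 1
    which(vapply(seq_len(max(n, 0)),
                 function(i) substr(seq, i, i + nchar(pep) - 1) == pep,
                 logical(1)))
  }
  set.seed(11)
  for (rep in 1:25) {
    seq <- paste(sample(c("A", "P", "G"), 40, replace = TRUE), collapse = "")
    pep <- paste(sample(c("A", "P"), sample(1:3, 1), replace = TRUE),
                 collapse = "")
    prec <- tibble::tibble(name = "x", sequence = seq, offset = 1L)
    hits <- locate_fragment(pep, prec)
    expect_equal(hits$start, brute(pep, seq))
    # substring extraction reproduces the query at every reported hit
    if (nrow(hits) > 0) {
      expect_true(all(substr(seq, hits$start, hits$end) == pep))
    }
  }
  prec <- tibble::tibble(name = "x", sequence = "AIPPA", offset = 60L)
  expect_equal(locate_fragment("IPP", prec)$start, 61L)
})

test_that("the transcribed identification table validates against the mature caseins", {
  peps <- fixture_peptides()
  expect_equal(length(unique(peps$sequence)), 49L)
  expect_equal(nrow(validate_assignments(peps, fixture_caseins())), 0L)
})

test_that("validate_assignments flags each class of violation", {
  caseins <- fixture_caseins()
  bad <- tibble::tibble(
    sequence = c("IPP", "IPP", "IPP", "DKIHPF"),
    precursor = c("beta-casein", "beta-casein", "no-such-protein", "beta-casein"),
    start = c(1L, 74L, 74L, 47L),
    end = c(3L, 78L, 76L, 52L),
    samples = rep(list("PR12"), 4))
  v <- validate_assignments(bad, caseins)
  expect_equal(nrow(v), 3L)
  expect_match(v$problem[v$row == 1], "residues 1-3 are REL")
  expect_match(v$problem[v$row == 2], "span length")
  expect_match(v$problem[v$row == 3], "unknown precursor")
})

test_that("peptide tables round-trip losslessly through TSV", {
  set.seed(5)
  caseins <- fixture_caseins()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  for (rep in 1:5) {
    n <- sample(1:20, 1)
    start <- sample(1:190, n, replace = TRUE)
    len <- sample(3:8, n, replace = TRUE)
    tab <- tibble::tibble(
      sequence = substr(caseins$sequence[1], start, start + len - 1),
      precursor = "beta-casein",
      start = as.integer(start),
      end = as.integer(start + len - 1),
      samples = replicate(n, sample(pr_samples, sample(1:4, 1)),
                          simplify = FALSE),
      modifications = replicate(n, character(0), simplify = FALSE))
    tab$samples <- lapply(tab$samples, sort)
    write_peptide_table(tab, tmp)
    expect_equal(read_peptide_table(tmp), tab)
  }
})

test_that("empty and malformed peptide tables are handled", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sequence\tprecursor\tstart\tend\tsamples", tmp)
  expect_equal(nrow(read_peptide_table(tmp)), 0L)
  writeLines(c("sequence\tprecursor\tstart\tend\tsamples",
               "IPP\tbeta-casein\tseventy\t76\tPR12"), tmp)
  expect_error(read_peptide_table(tmp), "malformed coordinates.*row")
  writeLines(c("sequence\tstart\tend", "IPP\t74\t76"), tmp)
  expect_error(read_peptide_table(tmp), "missing column")
})

test_that("modified sequences are extracted for screening exclusion", {
  tab <- tibble::tibble(
    sequence = c("IPP", "EMPFPK"), precursor = "beta-casein",
    start = c(74L, 108L), end = c(76L, 113L),
    samples = list("PR12", "PR12"),
    modifications = list(character(0), "2:oxidation"))
  expect_equal(modified_sequences(tab), "EMPFPK")
})
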