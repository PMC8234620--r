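# shared fixture loaders and small generators used across test files

fixture_caseins <- function() {
  read_precursors(pepscreen_extdata("caseins_mature.fasta"))
}

fixture_peptides <- function() {
  read_peptide_table(pepscreen_extdata("pr_bioactive_peptides.tsv"))
}

fixture_reference <- function() {
  read_bioactivity_reference(pepscreen_extdata("bioactivity_reference.tsv"))
}

pr_samples <- c("PR12", "PR18", "PR24", "PR30")

# the named screening sets and their expected final candidates
dppiv_consensus_set <- c("FALPQ", "IPPLT", "LPLP", "IPP", "LPPT", "APFPE", "IPPL")
glucosidase_feature_set <- c("KIHPF", "IHPF", "DKIHPF", "EPF", "PPF", "VVPPF", "VVVPPF")
stability_calls <- c(
  FALPQ = FALSE, IPPLT = FALSE, LPLP = FALSE, IPP = TRUE, LPPT = TRUE,
  APFPE = TRUE, KIHPF = FALSE, IHPF = FALSE, DKIHPF = FALSE, EPF = FALSE,
  PPF = TRUE, VVPPF = TRUE, VVVPPF = TRUE)

# a score table on which every sequence passes score/length/docking
passing_scores <- function(sequences) {
  tibble::tibble(sequence = sequences, ranker_score = 0.9,
                 p_dppiv = 1e-4, p_glucosidase = 1e-4, p_amylase = 1e-4)
}

random_peptides <- function(n, min_len = 2, max_len = 15) {
  vapply(seq_len(n), function(i) {
    paste(sample(aa_alphabet(), sample(min_len:max_len, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}
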