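test_that("filter cascade applies strict thresholds per stage", {
  scores <- tibble::tibble(
    sequence = c("IPP", "VPP", "LEE"),
    ranker_score = c(0.9, 0.5, 0.2),
    p_dppiv = c(1e-4, 1e-4, 1e-4))
  out <- filter_cascade(scores, screening_config(targets = "DPP-IV"))
  expect_equal(out$sequence[out$retained], "IPP")  # 0.5 is not > 0.5

  long <- passing_scores(c("RPKHPIKHQGLPQEVLNENLLRF", "IPP"))
  out <- filter_cascade(long, screening_config(targets = "DPP-IV"))
  expect_false(out$retained[1])  # 23 residues exceeds the length cap
  expect_false(out$pass_length[1])

  boundary <- tibble::tibble(sequence = "IPP", ranker_score = 0.9,
                             p_dppiv = 0.01)
  out <- filter_cascade(boundary, screening_config(targets = "DPP-IV"))
  expect_false(out$retained)  # p must be strictly below alpha
})

test_that("modified peptides and missing docking columns are excluded", {
  scores <- passing_scores(c("IPP", "EMPFPK"))
  out <- filter_cascade(scores, screening_config(targets = "DPP-IV"),
                        modified = "EMPFPK")
  expect_equal(out$sequence[out$retained], "IPP")
  expect_true(out$excluded_modified[out$sequence == "EMPFPK"])

  no_col <- tibble::tibble(sequence = "IPP", ranker_score = 0.9)
  expect_warning(out <- filter_cascade(no_col,
                                       screening_config(targets = "DPP-IV")),
                 "lack a docking p-value")
  expect_false(out$retained)
})

test_that("cascade is monotone under threshold loosening", {
  set.seed(23)
  seqs <- unique(random_peptides(60, 2, 14))
  scores <- simulate_scores(seqs, frac_active = 0.5, frac_binding = 0.5,
                            seed = 23)
  tight <- filter_cascade(scores, screening_config(
    score_threshold = 0.6, max_length = 8, docking_alpha = 0.005))
  loose <- filter_cascade(scores, screening_config(
    score_threshold = 0.4, max_length = 12, docking_alpha = 0.05))
  key <- function(x) paste(x$sequence, x$target)
  expect_true(all(key(tight)[tight$retained] %in% key(loose)[loose$retained]))
})

test_that("DPP-IV consensus passes the seven candidate peptides", {
  verdict <- dppiv_consensus(dppiv_consensus_set)
  expect_true(all(verdict$pass))
  expect_false(dppiv_consensus("GTQY")$pass)  # G is not branched-chain
  short <- dppiv_consensus("A")
  expect_false(short$pass)
  expect_match(short$reason, "length")
})

test_that("exactly 12 of the 400 two-residue prefixes satisfy the DPP-IV consensus", {
  prefixes <- as.vector(outer(aa_alphabet(), aa_alphabet(), paste0))
  expect_length(prefixes, 400L)
  expect_equal(sum(dppiv_consensus(prefixes)$pass), 12L)  # 6 x 2
})

test_that("alpha-glucosidase features pass the seven candidate peptides", {
  verdict <- glucosidase_features(glucosidase_feature_set)
  expect_true(all(verdict$pass))
  expect_equal(verdict$n_features[verdict$sequence == "KIHPF"], 3L)
  ppf <- glucosidase_features("PPF")
  expect_true(ppf$pass)
  expect_false(ppf$f1_n_terminal)
  expect_false(glucosidase_features("GGG")$pass)
})

test_that("consensus verdicts agree with brute-force predicate evaluation", {
  set.seed(41)
  seqs <- random_peptides(300, 2, 12)
  d <- dppiv_consensus(seqs)
  g <- glucosidase_features(seqs)
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    n <- length(ch)
    expect_equal(d$pass[i],
                 ch[1] %in% c("I", "L", "A", "M", "F", "W") &&
                   ch[2] %in% c("P", "A"))
    feats <- sum(ch[1] %in% c("S", "T", "Y", "K", "R"),
                 ch[n] %in% c("M", "A", "F"),
                 "P" %in% ch[max(1, n - 2):n])
    expect_equal(g$pass[i], feats >= 2)
    expect_equal(g$n_features[i], feats)
  }
})

test_that("the proline window of the glucosidase rule is configurable", {
  # P sits 4 positions from the C-terminus: fails at window 3, passes at 4
  expect_false(glucosidase_features("KPAAA")$f3_proline)
  expect_true(glucosidase_features("KPAAA", p_window = 4)$f3_proline)
})
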