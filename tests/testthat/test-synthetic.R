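test_that("simulated peptidomes hit their totals and shared core exactly", {
  samples <- tibble::tibble(sample = pr_samples,
                            ripening_months = c(12L, 18L, 24L, 30L),
                            total = c(283L, 292L, 309L, 312L))
  peps <- simulate_peptidome(samples = samples, n_core = 228L, seed = 101)
  sets <- peptide_sets(peps)
  expect_equal(unname(lengths(sets)), samples$total)
  vp <- venn_partition(sets)
  expect_equal(vp$count[vp$n_samples == 4], 228L)
  # sample-unique regions account for the remainder
  expect_equal(sum(vp$count), 228L + sum(samples$total - 228L))
})

test_that("simulated peptides validate against their precursors by construction", {
  peps <- simulate_peptidome(seed = 55)
  expect_equal(nrow(validate_assignments(peps, fixture_caseins())), 0L)
})

test_that("generators are seed-deterministic", {
  a <- simulate_peptidome(seed = 9)
  b <- simulate_peptidome(seed = 9)
  attr(a, "sim_config") <- attr(b, "sim_config") <- NULL
  expect_identical(a, b)
  expect_false(identical(a$sequence, simulate_peptidome(seed = 10)$sequence))

  s1 <- simulate_scores(c("IPP", "LPPT", "APFPE"), seed = 3)
  s2 <- simulate_scores(c("IPP", "LPPT", "APFPE"), seed = 3)
  expect_identical(s1, s2)

  d1 <- simulate_dose_response(2, seed = 5)
  d2 <- simulate_dose_response(2, seed = 5)
  expect_identical(d1, d2)
})

test_that("a core fraction of one with equal totals gives identical sets", {
  samples <- tibble::tibble(sample = c("a", "b", "c"),
                            ripening_months = c(1L, 2L, 3L),
                            total = c(50L, 50L, 50L))
  peps <- simulate_peptidome(samples = samples, core_fraction = 1, seed = 2)
  sets <- peptide_sets(peps)
  expect_equal(sets$a, sets$b)
  expect_equal(sets$b, sets$c)
  expect_length(sets$a, 50L)
})

test_that("a requested core fraction is realised within rounding", {
  samples <- tibble::tibble(sample = pr_samples,
                            ripening_months = c(12L, 18L, 24L, 30L),
                            total = c(283L, 292L, 309L, 312L))
  for (f in c(0.3, 0.549, 0.8)) {
    peps <- simulate_peptidome(samples = samples, core_fraction = f,
                               seed = 7)
    sets <- peptide_sets(peps)
    vp <- venn_partition(sets)
    core <- vp$count[vp$n_samples == 4]
    union_size <- sum(vp$count)
    # integer core with exact totals: deviation bounded by (1 + 3f)/2
    expect_lte(abs(core - f * union_size), (1 + 3 * f) / 2 + 1e-9)
  }
  # at the study's shared-core fraction the target is hit within one peptide
  peps <- simulate_peptidome(samples = samples, core_fraction = 0.549,
                             seed = 8)
  vp <- venn_partition(peptide_sets(peps))
  expect_lte(abs(vp$count[vp$n_samples == 4] - 0.549 * sum(vp$count)), 1)
})

test_that("an infeasible core raises an error", {
  samples <- tibble::tibble(sample = c("a", "b"), ripening_months = c(1L, 2L),
                            total = c(10L, 40L))
  expect_error(simulate_peptidome(samples = samples, n_core = 20L, seed = 1),
               "larger than the smallest sample")
})

test_that("score simulation respects the configured pass fractions", {
  set.seed(99)
  seqs <- unique(random_peptides(1200, 3, 10))
  none <- simulate_scores(seqs, frac_active = 0, seed = 12)
  out <- filter_cascade(none, screening_config())
  expect_equal(sum(out$retained), 0L)

  all_in <- simulate_scores(seqs, frac_active = 1, frac_binding = 1, seed = 12)
  out <- filter_cascade(all_in, screening_config())
  expect_true(all(out$retained[nchar(out$sequence) <= 10]))

  n <- 1000
  some <- simulate_scores(seqs[seq_len(n)], frac_active = 0.3, seed = 13)
  hits <- sum(some$ranker_score > 0.5)
  # binomial 99% bounds at n = 1000, p = 0.3
  expect_gte(hits, qbinom(0.005, n, 0.3))
  expect_lte(hits, qbinom(0.995, n, 0.3))
})

test_that("the demo dataset round-trips through the pipeline readers", {
  dir <- withr::local_tempdir()
  paths <- write_demo_fixtures(dir, seed = 4)
  expect_true(all(file.exists(paths)))
  peps <- read_peptide_table(paths[["peptides"]])
  expect_gt(nrow(peps), 0)
  expect_equal(nrow(validate_assignments(peps, read_precursors(paths[["precursors"]]))), 0L)
  scores <- read_screening_scores(paths[["scores"]])
  expect_true(all(scores$ranker_score >= 0 & scores$ranker_score <= 1))
  curves <- read_dose_response(paths[["dose_response"]])
  expect_equal(length(unique(curves$analyte)), 6L)
})
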