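test_that("pair statistic matches direct G-test evaluation", {
  # factorizing joint counts: AU, AC, GU, GC twice each -> independence
  ind <- rna_alignment(c("AU", "AU", "AC", "AC", "GU", "GU", "GC", "GC"))
  expect_equal(pair_statistic(ind, 1, 2), 0)

  # perfectly coupled two-level columns: G = 16 ln 2
  dep <- rna_alignment(c("AU", "AU", "AU", "AU", "GC", "GC", "GC", "GC"))
  expect_equal(pair_statistic(dep, 1, 2), 16 * log(2), tolerance = 1e-12)

  # permutation of rows leaves G unchanged
  perm <- rna_alignment(dep$seq[c(5, 1, 8, 2, 3, 6, 4, 7)])
  expect_equal(pair_statistic(perm, 1, 2), pair_statistic(dep, 1, 2))

  # agreement with an independent contingency-table evaluation,
  # gap exclusion included
  set.seed(31)
  for (rep in 1:20) {
    chars <- sample(c("A", "C", "G", "U", "-"), 24, replace = TRUE)
    aln <- rna_alignment(apply(matrix(chars, 12), 1, paste, collapse = ""))
    g <- pair_statistic(aln, 1, 2)
    x <- substr(aln$seq, 1, 1); y <- substr(aln$seq, 2, 2)
    expect_equal(g, oracle_g_stat(x, y), tolerance = 1e-10)
    expect_gte(g, 0)
  }

  # fewer than 2 gap-free rows -> 0
  sparse <- rna_alignment(c("A-", "-U", "-C"))
  expect_equal(pair_statistic(sparse, 1, 2), 0)
})

test_that("substitution counts use the majority residue with alphabetical ties", {
  expect_equal(substitution_counts(rna_alignment(c("A", "A", "A", "A")), 1), 0L)
  expect_equal(substitution_counts(rna_alignment(c("A", "A", "G", "G")), 1), 2L)
  expect_equal(substitution_counts(rna_alignment(c("A", "G", "C", "U")), 1), 3L)
  # gaps are not substitutions
  expect_equal(substitution_counts(rna_alignment(c("A", "-", "G", ".")), 1), 1L)
})

test_that("null calibration is seeded, validated, and well calibrated", {
  aln <- simulate_unstructured_alignment(20L, 12L, seed = 9L)
  expect_error(calibrate_null(aln, n_null = 0L, seed = 1L), "n_null")
  expect_error(calibrate_null(rna_alignment("A"), 5L, 1L), "2 columns")

  c1 <- calibrate_null(aln, n_null = 10L, seed = 5L)
  c2 <- calibrate_null(aln, n_null = 10L, seed = 5L)
  expect_identical(c1$null_stats, c2$null_stats)

  # the empirical P of the pooled null at its own 95th percentile is 0.05
  # up to the add-one correction (direct-quantile oracle)
  q95 <- quantile(c1$null_stats, 0.95, names = FALSE)
  p <- pair_evalue(q95, c1, n_pairs_tested = 1L)
  expect_equal(p, mean(c1$null_stats >= q95 - 1e-12), tolerance = 0.05)
})

test_that("E-values behave like expected counts", {
  calib <- null_calibration(c(0.5, 1.2, 2.0, 3.3, 5.1), fit_tail = FALSE)
  np <- 100L
  expect_equal(pair_evalue(0, calib, np), np)
  # above every null statistic without a tail fit: add-one bound
  expect_equal(pair_evalue(10, calib, np), np * 1 / 6)
  # monotone non-increasing and bounded by the number of pairs
  grid <- seq(0, 10, by = 0.25)
  ev <- vapply(grid, pair_evalue, numeric(1), calib = calib,
               n_pairs_tested = np)
  expect_true(all(diff(ev) <= 1e-12))
  expect_true(all(ev <= np))
})

test_that("pair annotation flags significance, power and negatives coherently", {
  # fully conserved alignment: no variation, so no power and no signal
  cons <- rna_alignment(rep("GGGAAACCC", 15))
  p <- annotate_pairs(cons, n_null = 5L, seed = 2L)
  expect_false(any(p$is_significant))
  expect_false(any(p$has_power))
  expect_false(any(p$is_negative))

  # planted compensatory stem: its pairs dominate the statistic ranking
  aln <- simulate_structured_alignment(
    structured_aln_spec(n_seqs = 40L, length = 60L,
                        stems = list(c(10L, 40L, 5L)),
                        per_site_sub_prob = 0.35,
                        compensation_prob = 1, seed = 11L))
  p2 <- annotate_pairs(aln, seed = 3L)
  planted <- paste(10:14, 40:36)
  ranks <- rank(-p2$stat)[paste(p2$i, p2$j) %in% planted]
  expect_true(all(ranks <= 5))

  # is_negative implies not significant; determinism is bit-identical
  expect_false(any(p2$is_negative & p2$is_significant))
  p3 <- annotate_pairs(aln, seed = 3L)
  expect_identical(p2, p3)
})

test_that("pair report writer emits the documented columns", {
  aln <- simulate_unstructured_alignment(10L, 8L, seed = 1L)
  p <- annotate_pairs(aln, n_null = 5L, seed = 1L)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pair_report(p, f)
  back <- read.delim(f)
  expect_equal(names(back), c("i", "j", "stat", "evalue", "subs_i",
                              "subs_j", "power", "significant", "negative"))
  expect_equal(nrow(back), nrow(p))
})
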