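test_that("Fisher aggregation matches the chi-squared survival function", {
  # three-covariation reference case, quoted to two significant figures
  expect_equal(signif(fisher_aggregate(c(6.5e-7, 0.0053, 0.0204)), 2),
               2.1e-8)
  # closed form for n = 2 equal P-values
  expect_equal(fisher_aggregate(c(0.5, 0.5)), 0.59657, tolerance = 1e-5)

  # identity for a single P-value, to tight relative tolerance
  for (p in c(1e-6, 1e-4, 0.01, 0.3, 0.5, 0.9, 0.99)) {
    expect_equal(fisher_aggregate(p), p, tolerance = 1e-12)
  }

  # monotone: shrinking any p never increases the aggregate
  base <- c(0.2, 0.05, 0.7)
  for (k in 1:3) {
    smaller <- base; smaller[k] <- smaller[k] / 10
    expect_lte(fisher_aggregate(smaller), fisher_aggregate(base))
  }

  expect_error(fisher_aggregate(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_aggregate(1.2), "\\(0, 1\\]")
})

test_that("expected false positives is the tests-times-threshold product", {
  thr <- fisher_aggregate(c(6.5e-7, 0.0053, 0.0204))
  expect_equal(signif(expected_false_positives(134000, thr), 1), 0.003)
  expect_equal(expected_false_positives(10, 0), 0)
  expect_equal(expected_false_positives(1000, 0.05), 50)
})

fake_pairs <- function(i, j, evalue) {
  df <- data.frame(i = i, j = j, stat = 1, evalue = evalue,
                   subs_i = 3L, subs_j = 3L)
  df$has_power <- TRUE
  df$is_significant <- df$evalue <= 0.05
  df$is_negative <- FALSE
  class(df) <- c("pair_covariation", "data.frame")
  df
}

test_that("candidate criteria, rescue path and aggregation drive the verdict", {
  # structure: one 3-pair stem plus an isolated pair
  ss <- covscreen:::new_secondary_structure(
    rbind(c(1L, 30L), c(2L, 29L), c(3L, 28L), c(10L, 20L)),
    layers = rep(1L, 4), length = 30L)

  # 3 significant pairs, 2 of them stacked in one stem -> pass
  p <- fake_pairs(c(1L, 2L, 10L), c(30L, 29L, 20L), c(1e-3, 1e-2, 4e-2))
  v <- classify(p, ss)
  expect_equal(v$verdict, "pass")
  expect_equal(v$n_significant, 3L)
  expect_equal(v$max_same_stem, 2L)
  expect_equal(v$aggregated_p, fisher_aggregate(c(1e-3, 1e-2, 4e-2)))

  # 3 significant pairs in 3 distinct stems -> criterion (ii) fails
  ss3 <- covscreen:::new_secondary_structure(
    rbind(c(1L, 30L), c(10L, 20L), c(40L, 50L)),
    layers = rep(1L, 3), length = 50L)
  p3 <- fake_pairs(c(1L, 10L, 40L), c(30L, 20L, 50L), rep(1e-3, 3))
  expect_equal(classify(p3, ss3)$verdict, "fail")

  # a single extreme pair opens the rescue path
  pr <- fake_pairs(c(1L, 10L), c(30L, 20L), c(5e-5, 0.5))
  expect_equal(classify(pr, ss)$verdict, "rescue")

  # verdict is invariant under permutation of the pair rows
  vperm <- classify(p[c(3, 1, 2), ], ss)
  expect_equal(vperm$verdict, v$verdict)
  expect_equal(vperm$n_significant, v$n_significant)
  expect_equal(vperm$max_same_stem, v$max_same_stem)

  # E-values above 1 are clamped before aggregation and counted
  pclamp <- fake_pairs(c(1L, 2L, 10L), c(30L, 29L, 20L), c(1e-3, 1e-2, 4e-2))
  pclamp$evalue[3] <- 0.04
  vc <- classify(pclamp, ss, alpha = 0.05)
  expect_equal(vc$n_clamped, 0L)
})

test_that("codon-like covariation is counted on consensus distance", {
  p <- fake_pairs(c(1L, 4L, 7L, 10L, 2L), c(2L, 6L, 9L, 11L, 20L),
                  c(rep(1e-3, 4), 0.5))
  # distances 1,2,2,1 among significant pairs -> 4 > 3 flags
  f <- codon_covariation_filter(p)
  expect_true(f$flagged)
  expect_equal(f$n_codon_like, 4L)

  # exactly 3 short-range pairs stays unflagged (strict inequality)
  p3 <- fake_pairs(c(1L, 4L, 7L), c(2L, 6L, 9L), rep(1e-3, 3))
  expect_false(codon_covariation_filter(p3)$flagged)

  # no short-range significant pairs at all
  p0 <- fake_pairs(c(1L, 5L), c(20L, 40L), c(1e-3, 1e-3))
  f0 <- codon_covariation_filter(p0)
  expect_false(f0$flagged)
  expect_equal(f0$n_codon_like, 0L)

  # gap columns dropped from the consensus shrink apparent distances
  pmap <- fake_pairs(1L, 4L, 1e-3)
  f2 <- codon_covariation_filter(pmap, colmap = c(1L, NA, NA, 2L))
  expect_equal(f2$n_codon_like, 1L)
})

test_that("region windowing covers every screened position", {
  w <- window_region(2500)
  expect_equal(nrow(w), 4L)
  expect_true(all(w[, 2] - w[, 1] + 1 <= 1000))
  covered <- rep(FALSE, 2500)
  for (r in seq_len(nrow(w))) covered[w[r, 1]:w[r, 2]] <- TRUE
  expect_true(all(covered))

  expect_equal(window_region(1000), cbind(start = 1L, end = 1000L))
  expect_equal(nrow(window_region(99)), 0L)

  # coverage, bounds and window-size cap across a sweep of lengths
  set.seed(77)
  for (L in c(100, 999, 1000, 1001, 1499, 1500, 1501, 2500,
              sample(100:100000, 200))) {
    w <- window_region(L)
    expect_gte(nrow(w), 1L)
    expect_true(all(w >= 1 & w <= L))
    expect_true(all(w[, 2] - w[, 1] + 1 <= 1000))
    expect_equal(unname(w[1, 1]), 1L)
    expect_equal(unname(w[nrow(w), 2]), as.integer(L))
    if (nrow(w) > 1) {
      expect_true(all(w[-1, 1] <= w[-nrow(w), 2] + 1L))
    }
  }
})

test_that("flanked-mode caps trim toward the UTR/CDS junction", {
  utr <- covscreen:::region("chr1", 1000L, 3999L, "+", "three_prime_UTR")
  cds <- covscreen:::region("chr1", 4000L, 5799L, "+", "CDS")
  out <- prepare_flanked_query(utr, cds)
  # UTR keeps its 2000 nt nearest the CDS (the 3'-most ones here)
  expect_equal(c(out$utr_part$start, out$utr_part$end), c(2000L, 3999L))
  # CDS keeps its 1000 nt nearest the UTR
  expect_equal(c(out$cds_part$start, out$cds_part$end), c(4000L, 4999L))

  # below the caps nothing changes
  small_utr <- covscreen:::region("chr1", 3500L, 3999L, "+", "five_prime_UTR")
  out2 <- prepare_flanked_query(small_utr, cds)
  expect_equal(c(out2$utr_part$start, out2$utr_part$end), c(3500L, 3999L))

  # orientation with the CDS upstream of the UTR
  cds2 <- covscreen:::region("chr1", 100L, 1999L, "-", "CDS")
  utr2 <- covscreen:::region("chr1", 2000L, 4999L, "-", "three_prime_UTR")
  out3 <- prepare_flanked_query(utr2, cds2)
  expect_equal(c(out3$utr_part$start, out3$utr_part$end), c(2000L, 3999L))
  expect_equal(c(out3$cds_part$start, out3$cds_part$end), c(1000L, 1999L))

  far <- covscreen:::region("chr2", 1L, 10L, "+", "CDS")
  expect_error(prepare_flanked_query(utr, far), "contig")
  far2 <- covscreen:::region("chr1", 5000L, 5100L, "+", "CDS")
  expect_error(prepare_flanked_query(utr, far2), "adjacent")
})
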