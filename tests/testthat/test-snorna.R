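test_that("H and ACA box motifs are located with the 3'-terminal rule", {
  b <- find_boxes("GGAGAUUACA")
  expect_equal(c(b$aca_box$start, b$aca_box$end), c(8L, 10L))

  # an ACA only at the 5' end is not a tail box
  b2 <- find_boxes("ACAUCA", aca_window = 3L)
  expect_null(b2$aca_box)

  # ANANNA matches AGAGGA; the last qualifying match is reported
  b3 <- find_boxes("CCAGAGGACCCCCCCCUUACA")
  expect_equal(b3$h_box$matched_text, "AGAGGA")
  expect_equal(b3$h_box$start, 3L)
  expect_true(grepl("^A.A..A$", b3$h_box$matched_text))
  expect_equal(c(b3$aca_box$start, b3$aca_box$end), c(19L, 21L))
})

test_that("guide-target search finds planted pockets and only them", {
  for (s in c(3L, 17L, 41L)) {
    fx <- make_snorna_fixture(s)
    hits <- guide_target_search(fx$guide5, fx$guide3, fx$target)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$target_pos, fx$psi_pos)
    expect_true(revalidate_match(fx$guide5, fx$guide3, fx$target,
                                 hits$target_pos))
    # every reported position must survive the brute-force check
    all_u <- which(strsplit(fx$target, "")[[1]] == "U")
    brute <- all_u[vapply(all_u, function(u) {
      revalidate_match(fx$guide5, fx$guide3, fx$target, u)
    }, logical(1))]
    expect_equal(hits$target_pos, brute)

    # ablating the pocket uridine removes the match
    abl <- fx$target
    substr(abl, fx$psi_pos, fx$psi_pos) <- "C"
    expect_equal(nrow(guide_target_search(fx$guide5, fx$guide3, abl)), 0L)
  }

  # psi must be a U: a U-free target yields nothing
  expect_equal(nrow(guide_target_search("ACGA", "GCCA", "GGCCAAGGCC")), 0L)

  # breaking the 4th upstream pair leaves a 3-bp left flank: rejected
  fx <- make_snorna_fixture(7L)
  g3_4 <- substr(fx$guide3, 4L, 4L)
  nonpair <- if (g3_4 == "U") "C" else "A"
  brk <- fx$target
  substr(brk, fx$psi_pos - 4L, fx$psi_pos - 4L) <- nonpair
  hits3 <- guide_target_search(fx$guide5, fx$guide3, brk)
  expect_false(fx$psi_pos %in% hits3$target_pos)

  expect_error(guide_target_search("", "ACGU", "ACGU"), "empty guide")
})

test_that("wobble pairs are allowed and counted", {
  # pocket built with two G:U wobbles in the left flank
  # target upstream of psi (reading t-1, t-2, t-3, t-4): U G U G
  # guide3:                                              G U G U -> all wobble
  target <- paste0("CCC", "GUGU", "U", "A", "GGGG", "CCC")
  #                 1-3   4-7    8    9   10-13  14-16
  hits <- guide_target_search(guide5 = "ACCCC", guide3 = "GUGU",
                              target = target, min_bp = 4L)
  expect_true(8L %in% hits$target_pos)
  h <- hits[hits$target_pos == 8L, ]
  expect_equal(h$left_bp, 4L)
  expect_equal(h$n_wobble, 4L)
})

test_that("shuffle FPR is seeded, bounded and agrees with a re-implementation", {
  fx <- make_snorna_fixture(11L, target_len = 80L, flank = 6L)
  obs <- guide_target_search(fx$guide5, fx$guide3, fx$target)[1, ]

  expect_error(fpr_by_shuffle(fx$guide5, fx$guide3, fx$target, obs,
                              n_shuffles = 0L), "n_shuffles")

  f1 <- fpr_by_shuffle(fx$guide5, fx$guide3, fx$target, obs,
                       n_shuffles = 300L, seed = 11L)
  f2 <- fpr_by_shuffle(fx$guide5, fx$guide3, fx$target, obs,
                       n_shuffles = 300L, seed = 11L)
  expect_identical(f1, f2)
  expect_gte(f1, 0); expect_lte(f1, 1)

  # independent second implementation of the rejection loop, same seed
  # discipline (set.seed once, one sample.int per shuffle)
  oracle <- local({
    tgt <- strsplit(fx$target, "")[[1]]
    set.seed(11L)
    hit <- 0L
    for (b in 1:300) {
      sh <- paste(tgt[sample.int(length(tgt))], collapse = "")
      m <- guide_target_search(fx$guide5, fx$guide3, sh)
      if (nrow(m) && any(m$left_bp + m$right_bp >= obs$left_bp + obs$right_bp &
                         m$n_wobble <= obs$n_wobble)) hit <- hit + 1L
    }
    hit / 300
  })
  expect_equal(f1, oracle)

  # a stricter required total can only lower the FPR
  harder <- obs; harder$left_bp <- harder$left_bp + 2L
  f3 <- fpr_by_shuffle(fx$guide5, fx$guide3, fx$target, harder,
                       n_shuffles = 300L, seed = 11L)
  expect_lte(f3, f1)

  # all-N guides can never pair
  expect_equal(fpr_by_shuffle("NNNNN", "NNNNN", fx$target, obs,
                              n_shuffles = 50L, seed = 2L), 0)

  # degenerate zero-pair requirement is satisfied by every shuffle
  degen <- list(left_bp = 0L, right_bp = 0L, n_wobble = 100L)
  expect_equal(fpr_by_shuffle(fx$guide5, fx$guide3, fx$target, degen,
                              n_shuffles = 50L, seed = 2L), 1)
})
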