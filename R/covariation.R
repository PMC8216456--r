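#' Covariation statistic for one column pair
#'
#' G-test of independence over the 4x4 joint residue counts of two
#' alignment columns, computed on rows where neither position is a gap
#' (or an ambiguous `N`):
#' \deqn{G = 2 \sum_{ab} n_{ab} \log\frac{n_{ab} N}{n_a n_b}}
#' with zero-count cells contributing 0. `G = 0` exactly when the joint
#' counts factorize (no association), and whenever fewer than 2 usable rows
#' remain. Correlated compensatory substitutions at a conserved base pair
#' drive G up; the statistic is invariant under row permutation.
#'
#' @param aln an [rna_alignment].
#' @param i,j 1-based column indices, `i < j`.
#' @return non-negative numeric.
#' @export
pair_statistic <- function(aln, i, j) {
  stopifnot(i >= 1L, j > i, j <= n_columns(aln))
  cpp_pair_g(aln_codes(aln), as.integer(i), as.integer(j))
}

#' Per-column substitution count
#'
#' Number of gap-free rows whose residue differs from the column's majority
#' residue (ties broken alphabetically, A < C < G < U). Used as the
#' variation ("power") proxy: a column pair can only display compensatory
#' substitutions if both of its columns vary.
#'
#' @param aln an [rna_alignment].
#' @param i 1-based column index.
#' @return integer in `[0, n_rows]`.
#' @export
substitution_counts <- function(aln, i) {
  stopifnot(i >= 1L, i <= n_columns(aln))
  col <- aln_codes(aln)[, i]
  res <- col[col %in% 1:4]
  if (!length(res)) return(0L)
  counts <- tabulate(res, nbins = 4L)
  as.integer(length(res) - max(counts))
}

#' Calibrate the permutation null for an alignment
#'
#' Generates `n_null` column-shuffled versions of the alignment (the
#' negative-control construction: covariation destroyed, per-column base
#' composition preserved), computes the pair statistic for every column
#' pair of each, and pools the results into an empirical null
#' distribution. A gamma tail is fitted to the exceedances over the 95%
#' null quantile (method of moments, location at the threshold) so that
#' survival probabilities can be extrapolated beyond the largest pooled
#' statistic.
#'
#' The permutation null is exact for alignments of independently evolving
#' rows; for strongly phylogenetically structured alignments it is
#' anti-conservative (see the package vignette). Externally computed null
#' statistics (e.g. from a tree-aware simulator) can be supplied to
#' [pair_evalue()] via `null_calibration(stats = ...)`.
#'
#' @param aln an [rna_alignment] with at least 2 columns.
#' @param n_null number of shuffled alignments (>= 1).
#' @param seed integer seed; replicate seeds are derived as `seed + 1..n_null`.
#' @param fit_tail fit the gamma tail (default TRUE).
#' @return a `null_calibration` object.
#' @export
calibrate_null <- function(aln, n_null, seed, fit_tail = TRUE) {
  if (n_columns(aln) < 2L) stop("need >= 2 columns to calibrate", call. = FALSE)
  if (n_null < 1L) stop("n_null must be >= 1", call. = FALSE)
  nr <- n_rows(aln)
  stack <- do.call(rbind, lapply(seq_len(n_null), function(b) {
    aln_codes(shuffle_columns(aln, seed + b))
  }))
  stats <- cpp_pooled_null(stack, nr, n_null)
  null_calibration(stats, n_null = n_null, seed = seed, fit_tail = fit_tail)
}

#' @rdname calibrate_null
#' @param stats numeric vector of null statistics (hook for externally
#'   supplied nulls).
#' @export
null_calibration <- function(stats, n_null = NA_integer_, seed = NA_integer_,
                             fit_tail = TRUE) {
  stats <- as.numeric(stats)
  if (!length(stats)) stop("empty null statistics", call. = FALSE)
  tail_fit <- NULL
  if (fit_tail) tail_fit <- fit_gamma_tail(stats)
  structure(list(null_stats = sort(stats), n_null_alignments = n_null,
                 tail_fit = tail_fit, seed = seed),
            class = "null_calibration")
}

# Shifted-gamma fit to the exceedances over the 95% empirical quantile,
# by method of moments: shape = mean^2/var, scale = var/mean on
# (x - threshold). Degenerate tails (too few or constant exceedances)
# yield NULL and the add-one empirical rule is used instead.
fit_gamma_tail <- function(stats, q = 0.95) {
  thr <- stats::quantile(stats, q, names = FALSE, type = 7)
  exc <- stats[stats > thr] - thr
  if (length(exc) < 20L) return(NULL)
  m <- mean(exc); v <- stats::var(exc)
  if (!is.finite(v) || v <= 0 || m <= 0) return(NULL)
  list(shape = m^2 / v, scale = v / m, location = thr,
       tail_frac = length(exc) / length(stats))
}

#' E-value of a covariation statistic
#'
#' Expected number of column pairs at or above `stat` per alignment under
#' the permutation null: `E = n_pairs_tested * P_null(stat' >= stat)`.
#' The survival probability comes from the pooled empirical null with an
#' add-one correction, `(# null >= stat + 1) / (N + 1)`; statistics beyond
#' the largest pooled null statistic use the fitted gamma tail when
#' available, never exceeding the add-one bound. E is monotone
#' non-increasing in `stat` and never exceeds `n_pairs_tested`.
#'
#' @param stat non-negative statistic.
#' @param calib a `null_calibration`.
#' @param n_pairs_tested number of pairs in the tested alignment.
#' @return numeric E-value.
#' @export
pair_evalue <- function(stat, calib, n_pairs_tested) {
  ns <- calib$null_stats
  N <- length(ns)
  # sorted null: count >= stat via binary search
  n_ge <- N - findInterval(stat - 1e-12, ns)
  p <- (n_ge + 1) / (N + 1)
  if (n_ge == 0L && !is.null(calib$tail_fit)) {
    tf <- calib$tail_fit
    p_tail <- tf$tail_frac *
      stats::pgamma(stat - tf$location, shape = tf$shape, scale = tf$scale,
                    lower.tail = FALSE)
    p <- min(p, max(p_tail, 0))
  }
  n_pairs_tested * p
}

#' Annotate every column pair of an alignment
#'
#' Runs the full per-pair analysis: the G statistic for all pairs
#' `i < j`, E-values against a freshly calibrated (or supplied)
#' permutation null, per-column substitution counts, and the derived
#' calls. A pair is *significant* when `evalue <= alpha`; it *has power*
#' when both of its columns show at least `s_min` substitutions; it is a
#' *negative pair* (power but no covariation — evidence against a
#' conserved base pair, later excluded from folds) when it has power but
#' is not significant.
#'
#' @param aln an [rna_alignment] with >= 2 columns.
#' @param alpha per-pair E-value significance threshold (default 0.05).
#' @param s_min minimum per-column substitution count for power (default 2).
#' @param n_null shuffled alignments for the null (default 25).
#' @param seed integer seed for the null calibration.
#' @param calib optional pre-computed `null_calibration` (overrides
#'   `n_null`/`seed`).
#' @return data.frame of class `pair_covariation` with columns `i`, `j`,
#'   `stat`, `evalue`, `subs_i`, `subs_j`, `has_power`, `is_significant`,
#'   `is_negative`.
#' @export
annotate_pairs <- function(aln, alpha = 0.05, s_min = 2L, n_null = 25L,
                           seed = 1L, calib = NULL) {
  if (n_columns(aln) < 2L) stop("need >= 2 columns", call. = FALSE)
  if (is.null(calib)) calib <- calibrate_null(aln, n_null = n_null, seed = seed)
  m <- aln_codes(aln)
  g <- cpp_all_pairs_g(m)
  subs <- vapply(seq_len(n_columns(aln)), function(i) {
    substitution_counts(aln, i)
  }, integer(1L))
  # vectorized E-values over the sorted pooled null
  ns <- calib$null_stats
  N <- length(ns)
  n_ge <- N - findInterval(g[, "stat"] - 1e-12, ns)
  ev <- (n_ge + 1) / (N + 1)
  if (!is.null(calib$tail_fit)) {
    tf <- calib$tail_fit
    beyond <- n_ge == 0L
    if (any(beyond)) {
      p_tail <- tf$tail_frac *
        stats::pgamma(g[beyond, "stat"] - tf$location, shape = tf$shape,
                      scale = tf$scale, lower.tail = FALSE)
      ev[beyond] <- pmin(ev[beyond], pmax(p_tail, 0))
    }
  }
  np <- nrow(g)
  ev <- np * ev
  df <- data.frame(i = as.integer(g[, "i"]), j = as.integer(g[, "j"]),
                   stat = g[, "stat"], evalue = ev,
                   subs_i = subs[g[, "i"]], subs_j = subs[g[, "j"]])
  df$has_power <- pmin(df$subs_i, df$subs_j) >= s_min
  df$is_significant <- df$evalue <= alpha
  df$is_negative <- df$has_power & !df$is_significant
  attr(df, "alpha") <- alpha
  attr(df, "n_pairs_tested") <- np
  class(df) <- c("pair_covariation", "data.frame")
  df
}

#' Write a per-pair covariation report
#'
#' Tab-separated: `i`, `j`, `stat`, `evalue`, `subs_i`, `subs_j`, `power`,
#' `significant`, `negative`.
#'
#' @param pairs result of [annotate_pairs()].
#' @param path output path.
#' @export
write_pair_report <- function(pairs, path) {
  out <- data.frame(i = pairs$i, j = pairs$j,
                    stat = signif(pairs$stat, 6L),
                    evalue = signif(pairs$evalue, 6L),
                    subs_i = pairs$subs_i, subs_j = pairs$subs_j,
                    power = pairs$has_power,
                    significant = pairs$is_significant,
                    negative = pairs$is_negative)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
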