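#' Aggregate P-values with Fisher's method
#'
#' For independent P-values \eqn{p_1,\dots,p_n}, the quantity
#' \eqn{-2\sum_i \log p_i} follows a chi-squared distribution with
#' \eqn{2n} degrees of freedom; the aggregated P-value is its survival
#' function at the observed value. For a single P-value the aggregate
#' equals that P-value.
#'
#' @param p_values numeric vector, every element in `(0, 1]`.
#' @return aggregated P-value in `[0, 1]`.
#' @examples
#' fisher_aggregate(c(6.5e-7, 0.0053, 0.0204))  # ~2.1e-08
#' @export
fisher_aggregate <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (!length(p_values)) stop("no P-values to aggregate", call. = FALSE)
  if (any(p_values <= 0 | p_values > 1)) {
    stop("P-values must lie in (0, 1]", call. = FALSE)
  }
  stat <- -2 * sum(log(p_values))
  stats::pchisq(stat, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Expected false positives of a screen
#'
#' Under the null that none of the tested alignments contains a conserved
#' structure, the expected number of alignments crossing an aggregated
#' P-value threshold is simply `n_tests * p_threshold`.
#'
#' @param n_tests number of alignments tested.
#' @param p_threshold aggregated P-value threshold.
#' @return numeric.
#' @examples
#' expected_false_positives(134000, 2.1e-8)
#' @export
expected_false_positives <- function(n_tests, p_threshold) {
  stopifnot(n_tests >= 0, p_threshold >= 0, p_threshold <= 1)
  n_tests * p_threshold
}

#' Classify an alignment as a structural-RNA candidate
#'
#' Applies the two candidate criteria to an annotated pair set and its
#' constrained fold: *(i)* at least `min_sig` statistically significant
#' covarying pairs in total and *(ii)* at least `min_same_stem` of them in
#' the same stem of the proposed structure. Alignments failing both
#' criteria but holding at least one pair with an E-value below
#' `rescue_threshold` get a `rescue` verdict — in a full screen these are
#' re-examined with a structure-informed search before final judgement.
#'
#' Significant pairs' E-values are aggregated with [fisher_aggregate()]
#' (values above 1 are clamped to 1 first; the count of clamped values is
#' recorded).
#'
#' @param pairs a `pair_covariation` data.frame from [annotate_pairs()].
#' @param ss the `secondary_structure` proposed for the same alignment.
#' @param alpha significance threshold on pair E-values (default 0.05).
#' @param min_sig criterion (i) count (default 3).
#' @param min_same_stem criterion (ii) count (default 2).
#' @param rescue_threshold E-value for the rescue path (default 1e-4).
#' @param bulge_tol stem bulge tolerance passed to [stems()] (default 0).
#' @return a `candidate_verdict` list: `n_significant`, `max_same_stem`,
#'   `verdict` (`"pass"`, `"rescue"` or `"fail"`), `significant_evalues`,
#'   `aggregated_p`, `n_clamped`.
#' @export
classify <- function(pairs, ss, alpha = 0.05, min_sig = 3L,
                     min_same_stem = 2L, rescue_threshold = 1e-4,
                     bulge_tol = 0L) {
  sig <- pairs[pairs$evalue <= alpha, , drop = FALSE]
  n_sig <- nrow(sig)
  max_same <- 0L
  if (n_sig > 0L && NROW(ss$pairs) > 0L) {
    sig_key <- paste(sig$i, sig$j)
    for (st in stems(ss, bulge_tol = bulge_tol)) {
      k <- sum(paste(st[, 1L], st[, 2L]) %in% sig_key)
      if (k > max_same) max_same <- k
    }
  }
  verdict <- if (n_sig >= min_sig && max_same >= min_same_stem) {
    "pass"
  } else if (any(pairs$evalue < rescue_threshold)) {
    "rescue"
  } else "fail"
  agg <- NA_real_
  n_clamped <- 0L
  if (n_sig >= 1L) {
    ev <- sig$evalue
    n_clamped <- sum(ev > 1)
    agg <- fisher_aggregate(pmin(ev, 1))
  }
  structure(list(n_significant = n_sig, max_same_stem = as.integer(max_same),
                 verdict = verdict, significant_evalues = sig$evalue,
                 aggregated_p = agg, n_clamped = n_clamped),
            class = "candidate_verdict")
}

#' @export
print.candidate_verdict <- function(x, ...) {
  cat(sprintf(
    "candidate verdict: %s (%d significant pairs, %d in best stem%s)\n",
    toupper(x$verdict), x$n_significant, x$max_same_stem,
    if (!is.na(x$aggregated_p)) {
      sprintf("; aggregated P = %.3g", x$aggregated_p)
    } else ""))
  invisible(x)
}

#' Flag codon-like covariation
#'
#' Unannotated protein-coding regions show covariation between positions
#' one or two nucleotides apart (interactions within a codon). Alignments
#' with more than `max_allowed` significant pairs at consensus-position
#' distance 1 or 2 are flagged as likely coding and removed from the
#' structural-RNA candidate list. Distance is measured on ungapped
#' consensus positions, not raw alignment columns, so gap columns cannot
#' dilute the within-codon signal.
#'
#' @param pairs a `pair_covariation` data.frame.
#' @param colmap integer vector mapping alignment columns to consensus
#'   positions (`NA` for columns absent from the consensus), e.g. from an
#'   alignment via the internal >50%-gap display rule. Defaults to the
#'   identity if omitted.
#' @param alpha significance threshold (default 0.05).
#' @param max_allowed maximum tolerated codon-like pairs (default 3;
#'   flagging requires strictly more).
#' @return list `flagged` (logical), `n_codon_like` (integer).
#' @export
codon_covariation_filter <- function(pairs, colmap = NULL, alpha = 0.05,
                                     max_allowed = 3L) {
  sig <- pairs[pairs$evalue <= alpha, , drop = FALSE]
  if (is.null(colmap)) colmap <- seq_len(max(c(pairs$i, pairs$j, 0L)))
  pi <- colmap[sig$i]
  pj <- colmap[sig$j]
  d <- abs(pj - pi)
  n_codon <- sum(!is.na(d) & d %in% c(1L, 2L))
  list(flagged = n_codon > max_allowed, n_codon_like = as.integer(n_codon))
}

#' Window a region for screening
#'
#' Regions up to the window size are screened whole; longer ones are cut
#' into `window`-nt windows advancing by `window - overlap` nt, with a
#' final window ending at the region end so that every position is
#' covered. Regions shorter than `min_len` are skipped entirely (shorter
#' queries cannot reach the homology-search E-value threshold even for a
#' perfect match).
#'
#' @param region_length region length in nt (>= 1).
#' @param window window size (default 1000).
#' @param overlap overlap between consecutive windows (default 500).
#' @param min_len minimum screenable region length (default 100).
#' @return two-column integer matrix `(start, end)`, 1-based inclusive;
#'   zero rows when the region is below `min_len`.
#' @examples
#' window_region(2500)  # four windows
#' @export
window_region <- function(region_length, window = 1000L, overlap = 500L,
                          min_len = 100L) {
  stopifnot(region_length >= 1L, window > overlap)
  empty <- matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("start", "end")))
  if (region_length < min_len) return(empty)
  if (region_length <= window) {
    return(matrix(c(1L, region_length), 1L, 2L,
                  dimnames = list(NULL, c("start", "end"))))
  }
  step <- window - overlap
  starts <- seq.int(1L, region_length - window, by = step)
  last_end <- starts[length(starts)] + window - 1L
  if (last_end < region_length) {
    starts <- c(starts, region_length - window + 1L)
  }
  m <- cbind(start = as.integer(starts), end = as.integer(starts + window - 1L))
  m
}

#' Cap a UTR/CDS pair for the flanked mode
#'
#' For the flanked search mode, the (putative) UTR is restricted to at
#' most `utr_cap` nucleotides closest to its adjacent CDS, and the
#' flanking CDS to at most `cds_cap` nucleotides closest to the UTR.
#' Strand-aware: "closest" is measured at the shared boundary on the
#' genome, which the two regions must abut.
#'
#' @param utr,cds single-row region data.frames (see [read_region_table()]),
#'   adjacent on the same contig.
#' @param utr_cap maximum UTR length kept (default 2000).
#' @param cds_cap maximum CDS length kept (default 1000).
#' @return list `utr_part`, `cds_part` of capped region data.frames.
#' @export
prepare_flanked_query <- function(utr, cds, utr_cap = 2000L,
                                  cds_cap = 1000L) {
  stopifnot(nrow(utr) == 1L, nrow(cds) == 1L)
  if (utr$contig != cds$contig) {
    stop("UTR and CDS are on different contigs", call. = FALSE)
  }
  utr_first <- utr$end + 1L == cds$start   # UTR immediately upstream of CDS
  cds_first <- cds$end + 1L == utr$start   # CDS immediately upstream of UTR
  if (!utr_first && !cds_first) {
    stop("UTR and CDS are not adjacent", call. = FALSE)
  }
  trim_near_boundary <- function(reg, cap, boundary_on_right) {
    len <- reg$end - reg$start + 1L
    if (len > cap) {
      if (boundary_on_right) reg$start <- reg$end - cap + 1L
      else reg$end <- reg$start + cap - 1L
      reg$length <- cap
    }
    reg
  }
  list(utr_part = trim_near_boundary(utr, utr_cap, boundary_on_right = utr_first),
       cds_part = trim_near_boundary(cds, cds_cap, boundary_on_right = cds_first))
}
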