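# Independent oracles used across the suite. Each deliberately avoids the
# package's own code path for the quantity it checks.

# Exhaustive enumeration of every nested structure of a sequence:
# returns the maximum total weight over all pair sets in which no two
# pairs cross or share a position and hairpin loops span >= min_loop.
# Pure recursion without memoization, scoring each structure directly.
brute_force_fold_score <- function(consensus, min_loop = 3L,
                                   forced = NULL, excluded = NULL,
                                   bonus = NULL) {
  chars <- strsplit(toupper(consensus), "")[[1L]]
  L <- length(chars)
  can_pair <- function(a, b) {
    a == "N" || b == "N" ||
      paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  pair_w <- function(i, j) {
    if (!is.null(excluded) && NROW(excluded) &&
        any(excluded[, 1L] == i & excluded[, 2L] == j)) return(NA_real_)
    if (!can_pair(chars[i], chars[j]) || j - i - 1L < min_loop) {
      return(NA_real_)
    }
    w <- 1
    if (!is.null(bonus) && NROW(bonus)) {
      hit <- bonus[, 1L] == i & bonus[, 2L] == j
      if (any(hit)) w <- bonus[which(hit)[1L], 3L]
    }
    w
  }
  best <- -Inf
  n_forced <- if (is.null(forced)) 0L else NROW(forced)
  # enumerate structures as sets of pairs over positions i..j
  enum <- function(i, j) {
    if (i >= j) return(list(matrix(integer(0), 0L, 2L)))
    out <- lapply(enum(i + 1L, j), identity)   # i unpaired
    for (k in seq.int(i + 1L, j)) {
      if (is.na(pair_w(i, k))) next
      left <- enum(i + 1L, k - 1L)
      right <- enum(k + 1L, j)
      for (a in left) for (b in right) {
        out[[length(out) + 1L]] <- rbind(c(i, k), a, b)
      }
    }
    out
  }
  for (s in enum(1L, L)) {
    if (n_forced) {
      have <- apply(forced, 1L, function(f) {
        any(s[, 1L] == f[1L] & s[, 2L] == f[2L])
      })
      if (!all(have)) next
    }
    sc <- if (NROW(s)) {
      sum(apply(s, 1L, function(p) pair_w(p[1L], p[2L])))
    } else 0
    if (!is.na(sc) && sc > best) best <- sc
  }
  best
}

# Independent re-validation of a guide-target match by direct
# position-by-position comparison on character vectors.
revalidate_match <- function(guide5, guide3, target, pos, min_bp = 4L) {
  tg <- strsplit(toupper(target), "")[[1L]]
  g5 <- strsplit(toupper(guide5), "")[[1L]]
  g3 <- strsplit(toupper(guide3), "")[[1L]]
  pairs_ok <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  if (tg[pos] != "U") return(FALSE)
  left <- 0L
  for (k in seq_along(g3)) {
    if (pos - k < 1L || !pairs_ok(tg[pos - k], g3[k])) break
    left <- left + 1L
  }
  right <- 0L
  for (k in seq_along(g5)) {
    if (pos + 1L + k > length(tg) ||
        !pairs_ok(tg[pos + 1L + k], g5[length(g5) + 1L - k])) break
    right <- right + 1L
  }
  left >= min_bp && right >= min_bp
}

# Independent per-column permutation with the package's seed discipline
# (one set.seed, columns visited left to right, sample.int per column).
oracle_column_shuffle <- function(seqs, seed) {
  mat <- do.call(rbind, strsplit(seqs, ""))
  set.seed(seed)
  for (j in seq_len(ncol(mat))) {
    mat[, j] <- mat[sample.int(nrow(mat)), j]
  }
  apply(mat, 1L, paste, collapse = "")
}

# Direct evaluation of the G statistic from a contingency table.
oracle_g_stat <- function(x, y) {
  keep <- !(x %in% c("-", ".", "N")) & !(y %in% c("-", ".", "N"))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2L) return(0)
  tab <- table(x, y)
  N <- sum(tab)
  g <- 0
  for (a in rownames(tab)) for (b in colnames(tab)) {
    n <- tab[a, b]
    if (n > 0) g <- g + n * log(n * N / (sum(tab[a, ]) * sum(tab[, b])))
  }
  2 * g
}

toy_alignment <- function() {
  rna_alignment(c("GGGAAACCC", "GGCAAAGCC", "GGGAAUCCC"),
                seq_id = c("g1/1-9", "g2/1-9", "g3/1-9"),
                ss_cons = "<<<...>>>")
}
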