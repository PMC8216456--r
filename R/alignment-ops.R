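#' Extract the non-coding span of an alignment
#'
#' Column-slices an alignment to a span and keeps only rows that retain at
#' least `min_nt` non-gap residues inside it. This is the region surgery of
#' the flanked screening mode: after an initial coding-anchored homology
#' search, the non-coding columns are cut out and only sequences with
#' enough residues there seed the next search iteration.
#'
#' @param aln an [rna_alignment].
#' @param first_col,last_col 1-based inclusive column span.
#' @param min_nt minimum non-gap residue count for a row to survive
#'   (default 50). An empty result is returned as a 0-row alignment, not an
#'   error.
#' @return an [rna_alignment] restricted to the span.
#' @export
extract_noncoding_span <- function(aln, first_col, last_col, min_nt = 50L) {
  stopifnot(first_col >= 1L, last_col >= first_col,
            last_col <= n_columns(aln))
  sub <- substr(aln$seq, first_col, last_col)
  nres <- nchar(gsub("[.-]", "", sub))
  keep <- nres >= min_nt
  ss <- if (!is.null(aln$ss_cons)) {
    substr(aln$ss_cons, first_col, last_col)
  } else NULL
  # pairs severed by the slice would unbalance the annotation; drop it then
  if (!is.null(ss)) {
    ok <- tryCatch({check_balanced_ss(ss); TRUE}, error = function(e) FALSE)
    if (!ok) ss <- NULL
  }
  rna_alignment(sub[keep], seq_id = aln$seq_id[keep],
                genome_id = aln$genome_id[keep], score = aln$score[keep],
                ss_cons = ss)
}

#' Keep the top-scoring row per genome
#'
#' RNA pseudogenes are no longer structurally constrained and dilute the
#' covariation signal between conserved base pairs, so a screen keeps only
#' the best-scoring hit of each genome. Ties keep the row that appears
#' first; survivor order follows the input alignment.
#'
#' @param aln an [rna_alignment] whose rows carry `genome_id`, and scores
#'   wherever a genome has several rows.
#' @return an [rna_alignment] with pairwise-distinct genome ids.
#' @export
dedup_best_per_genome <- function(aln) {
  if (n_rows(aln) == 0L) return(aln)
  dup_genomes <- unique(aln$genome_id[duplicated(aln$genome_id)])
  if (any(is.na(aln$score[aln$genome_id %in% dup_genomes]))) {
    stop("genome with multiple rows but missing scores: cannot pick top hit",
         call. = FALSE)
  }
  keep <- logical(n_rows(aln))
  for (g in unique(aln$genome_id)) {
    idx <- which(aln$genome_id == g)
    if (length(idx) == 1L) keep[idx] <- TRUE
    else keep[idx[which.max(aln$score[idx])]] <- TRUE
  }
  rna_alignment(aln$seq[keep], seq_id = aln$seq_id[keep],
                genome_id = aln$genome_id[keep], score = aln$score[keep],
                ss_cons = aln$ss_cons)
}

#' Shuffle each alignment column independently
#'
#' Permutes the contents of every column (gaps included) independently
#' across rows. This destroys covariation between columns while preserving
#' per-column base composition and position-specific conservation exactly —
#' the negative-control construction of the screen, and the permutation
#' null behind the E-value calibration.
#'
#' @param aln an [rna_alignment].
#' @param seed integer seed; the same seed reproduces the same shuffle.
#' @return an [rna_alignment]; any `ss_cons` is carried through unchanged.
#' @export
shuffle_columns <- function(aln, seed) {
  n <- n_rows(aln)
  if (n <= 1L) return(aln)
  m <- aln_codes(aln)
  perm_m <- with_local_seed(seed, {
    for (j in seq_len(ncol(m))) {
      m[, j] <- m[sample.int(n), j]
    }
    m
  })
  rna_alignment(codes_to_seq(perm_m), seq_id = aln$seq_id,
                genome_id = aln$genome_id, score = aln$score,
                ss_cons = aln$ss_cons)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Majority-rule consensus sequence
#'
#' Per column, emits the most frequent residue when its gap-excluded
#' frequency reaches `min_frac`, otherwise `N`. Columns that are more than
#' half gaps are dropped from the consensus, mirroring the display
#' convention for alignment figures. Ties between residues are broken
#' alphabetically (A < C < G < U) for determinism.
#'
#' @param aln an [rna_alignment].
#' @param min_frac minimum gap-excluded majority frequency (default 0.5).
#' @return ungapped consensus string (possibly shorter than the alignment).
#' @export
consensus_sequence <- function(aln, min_frac = 0.5) {
  m <- aln_codes(aln)
  n <- nrow(m)
  out <- character(0)
  alpha <- c("A", "C", "G", "U")
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gaps <- sum(col == 0L)
    if (gaps > n / 2) next
    counts <- tabulate(col[col %in% 1:4], nbins = 4L)
    res <- sum(counts)
    if (res == 0L) next
    best <- which.max(counts)  # which.max takes the first, i.e. alphabetical
    out <- c(out, if (counts[best] / res >= min_frac) alpha[best] else "N")
  }
  paste(out, collapse = "")
}

# Map alignment columns to ungapped consensus-display positions: columns
# with more than 50% gaps get NA (not part of the consensus coordinate
# system), others are numbered consecutively. Mirrors the column rule of
# consensus_sequence() exactly.
consensus_column_map <- function(aln) {
  m <- aln_codes(aln)
  n <- nrow(m)
  shown <- vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    sum(col == 0L) <= n / 2 && any(col %in% 1:4)
  }, logical(1L))
  map <- rep(NA_integer_, ncol(m))
  map[shown] <- seq_len(sum(shown))
  map
}
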