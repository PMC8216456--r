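#' Locate H and ACA box motifs
#'
#' H/ACA snoRNAs carry an H box (consensus `ANANNA`, N any residue) in the
#' hinge between their two hairpins and an `ACA` box three nucleotides
#' from the 3' terminus. `find_boxes` reports the last `ANANNA` match
#' preceding the 3'-terminal region, and an `ACA` whose end lies within
#' `aca_window` nucleotides of the 3' terminus (i.e. among the last
#' `aca_window` positions). Either motif may be absent.
#'
#' @param seq ungapped RNA string.
#' @param aca_window length of the 3'-terminal region the ACA box must
#'   end in (default 5).
#' @return list with `h_box` (`start`, `end`, `matched_text` or `NULL`)
#'   and `aca_box` (`start`, `end` or `NULL`).
#' @export
find_boxes <- function(seq, aca_window = 5L) {
  seq <- toupper(gsub("T", "U", seq, fixed = TRUE))
  L <- nchar(seq)
  aca_box <- NULL
  m <- gregexpr("ACA", seq, fixed = TRUE)[[1L]]
  if (m[1L] != -1L) {
    ends <- m + 2L
    ok <- which(L - ends < aca_window)
    if (length(ok)) {
      k <- ok[length(ok)]
      aca_box <- list(start = as.integer(m[k]), end = as.integer(ends[k]))
    }
  }
  h_box <- NULL
  # H box search space: upstream of the ACA-box region (or the whole
  # sequence when no ACA box); take the last match
  limit <- if (!is.null(aca_box)) aca_box$start - 1L else L
  if (limit >= 6L) {
    sub <- substr(seq, 1L, limit)
    m <- gregexpr("(?=(A[ACGU]A[ACGU][ACGU]A))", sub, perl = TRUE)[[1L]]
    if (m[1L] != -1L) {
      st <- m[length(m)]
      h_box <- list(start = as.integer(st), end = as.integer(st + 5L),
                    matched_text = substr(seq, st, st + 5L))
    }
  }
  list(h_box = h_box, aca_box = aca_box)
}

#' Search a target RNA for pseudouridylation pockets
#'
#' Scans every uridine of `target` as a candidate pseudouridylation site
#' (ψ) and tests antiparallel complementarity to the two guide halves of
#' an H/ACA pseudouridylation pocket: the 3' guide half pairs the target
#' upstream of ψ (positions ψ-1, ψ-2, ... against successive guide3
#' residues) and the 5' guide half pairs the target downstream of ψ+1
#' (positions ψ+2, ψ+3, ... against guide5 read from its 3' end); ψ and
#' ψ+1 themselves stay unpaired, the canonical pocket geometry. A match
#' requires at least `min_bp` consecutive Watson-Crick or G:U wobble
#' pairs on each side with no internal mismatches; an `N` in a guide
#' terminates the run.
#'
#' @param guide5,guide3 5' and 3' guide-half sequences (definite residues
#'   or `N`), each non-empty.
#' @param target ungapped target RNA string.
#' @param min_bp minimum consecutive pairs per side (default 4).
#' @return data.frame with columns `target_pos` (ψ position), `left_bp`,
#'   `right_bp` (maximal run lengths), `n_wobble` (G:U pairs across both
#'   runs).
#' @export
guide_target_search <- function(guide5, guide3, target, min_bp = 4L) {
  if (!nchar(guide5) || !nchar(guide3)) {
    stop("empty guide half", call. = FALSE)
  }
  tg <- code_string(toupper(gsub("T", "U", target, fixed = TRUE)))
  g5 <- code_string(toupper(gsub("T", "U", guide5, fixed = TRUE)))
  g3 <- code_string(toupper(gsub("T", "U", guide3, fixed = TRUE)))
  m <- cpp_scan_guides(tg, g5, g3, as.integer(min_bp))
  data.frame(target_pos = m[, "pos"], left_bp = m[, "left_bp"],
             right_bp = m[, "right_bp"], n_wobble = m[, "n_wobble"])
}

#' Shuffle-based false positive rate for a guide-target match
#'
#' Estimates how often a match at least as good as the observed one
#' arises by chance: the target is shuffled (mononucleotide,
#' composition-preserving) `n_shuffles` times and the fraction of
#' shuffles containing at least one pocket with (i) as many total base
#' pairs (`left_bp + right_bp`) and (ii) no more wobble pairs than the
#' observed match is reported. Deterministic for a given seed.
#'
#' @param guide5,guide3 guide halves as in [guide_target_search()].
#' @param target the unshuffled target string.
#' @param observed one row of a [guide_target_search()] result (list or
#'   single-row data.frame with `left_bp`, `right_bp`, `n_wobble`).
#' @param n_shuffles number of shuffles (default 10000).
#' @param seed integer seed.
#' @param min_bp per-side minimum as in the original search (default 4).
#' @param dinucleotide preserve dinucleotide composition instead
#'   (default FALSE; the mononucleotide shuffle is the reference
#'   negative-control construction).
#' @return numeric in `[0, 1]`.
#' @export
fpr_by_shuffle <- function(guide5, guide3, target, observed,
                           n_shuffles = 10000L, seed = 1L, min_bp = 4L,
                           dinucleotide = FALSE) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1", call. = FALSE)
  tg <- code_string(toupper(gsub("T", "U", target, fixed = TRUE)))
  g5 <- code_string(toupper(gsub("T", "U", guide5, fixed = TRUE)))
  g3 <- code_string(toupper(gsub("T", "U", guide3, fixed = TRUE)))
  obs_total <- observed$left_bp + observed$right_bp
  obs_wob <- observed$n_wobble
  # a zero-pair requirement is met by every shuffle vacuously
  if (obs_total <= 0L) return(1)
  hits <- with_local_seed(seed, {
    n_hit <- 0L
    for (b in seq_len(n_shuffles)) {
      sh <- if (dinucleotide) dinuc_shuffle_codes(tg) else
        tg[sample.int(length(tg))]
      m <- cpp_scan_guides(sh, g5, g3, as.integer(min_bp))
      if (nrow(m) &&
          any(m[, "left_bp"] + m[, "right_bp"] >= obs_total &
              m[, "n_wobble"] <= obs_wob)) {
        n_hit <- n_hit + 1L
      }
    }
    n_hit
  })
  hits / n_shuffles
}

# Dinucleotide-preserving shuffle via a random Eulerian-ish walk on the
# transition multigraph (simple swap-based approximation: repeatedly
# proposes swaps that preserve flanking dinucleotides).
dinuc_shuffle_codes <- function(x) {
  n <- length(x)
  if (n < 4L) return(x)
  for (it in seq_len(4L * n)) {
    idx <- sample.int(n - 2L, 2L) + 1L
    i <- idx[1L]; j <- idx[2L]
    if (i == j) next
    if (x[i - 1L] == x[j - 1L] && x[i + 1L] == x[j + 1L]) {
      tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
    }
  }
  x
}
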