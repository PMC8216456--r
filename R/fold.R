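#' Covariation-constrained maximum-pairing fold
#'
#' Weighted Nussinov/CYK dynamic program over a consensus sequence. The
#' score of a nested structure is the sum of its pair weights: 1 per
#' eligible pair by default, plus a covariation bonus `w_cov` for pairs
#' listed in `weights`. Eligible pairs are Watson-Crick or G:U wobble
#' (`N` matches anything); hairpin loops span at least `min_loop`
#' unpaired positions.
#'
#' Constraints follow the covariation analysis: every *forced* pair
#' (statistically significant covariation) must appear in the output, and
#' every *excluded* pair (power but no covariation) is prohibited. Forced
#' pairs that cannot all nest together are assigned greedily, by
#' descending weight, to the primary layer first and then to additional
#' pseudoknot layers; the dynamic program then folds around the primary
#' layer's forced pairs. No forced pair is ever dropped.
#'
#' The scoring is deliberately not thermodynamic: the fold exists to
#' organize covarying pairs into stems for the candidate criteria, not to
#' predict minimum free energy.
#'
#' @param consensus ungapped consensus string over `A,C,G,U,N`.
#' @param forced two-column matrix of pairs that must be included
#'   (canonical/wobble in the consensus; pairwise disjoint positions).
#' @param excluded two-column matrix of prohibited pairs.
#' @param weights optional data.frame/matrix with columns `i`, `j`,
#'   `weight` giving per-pair total weights for listed pairs.
#' @param min_loop minimum hairpin loop length (default 3).
#' @param w_cov bonus weight added to forced pairs absent from `weights`
#'   (default 10).
#' @return a `secondary_structure`: list with `pairs` (two-column matrix),
#'   `layers` (integer layer per pair, 1 = nested primary),
#'   `dotbracket`, `length`, `score`.
#' @export
constrained_fold <- function(consensus, forced = NULL, excluded = NULL,
                             weights = NULL, min_loop = 3L, w_cov = 10) {
  consensus <- toupper(gsub("T", "U", consensus, fixed = TRUE))
  codes <- code_string(consensus)
  L <- length(codes)
  forced <- as_pair_matrix(forced)
  excluded <- as_pair_matrix(excluded)
  check_forced(forced, excluded, codes, min_loop)

  w <- eligibility_weights(codes, min_loop)
  if (!is.null(weights) && NROW(weights) > 0L) {
    weights <- as.data.frame(weights)
    for (r in seq_len(nrow(weights))) {
      i <- weights$i[r]; j <- weights$j[r]
      if (w[i, j] >= 0) w[i, j] <- weights$weight[r]
    }
  }
  for (r in seq_len(NROW(excluded))) {
    w[excluded[r, 1L], excluded[r, 2L]] <- -1
  }

  # split forced pairs into a mutually nested primary set plus
  # pseudoknot layers, greedily by descending weight
  wkey <- if (!is.null(weights) && NROW(weights) > 0L) {
    stats::setNames(weights$weight, paste(weights$i, weights$j))
  } else numeric(0)
  f_weight <- if (NROW(forced)) {
    vapply(seq_len(nrow(forced)), function(r) {
      k <- paste(forced[r, 1L], forced[r, 2L])
      if (k %in% names(wkey)) unname(wkey[[k]]) else 1 + w_cov
    }, numeric(1L))
  } else numeric(0)
  f_layer <- assign_layers(forced, f_weight)
  primary_forced <- forced[f_layer == 1L, , drop = FALSE]

  # force inclusion: big bonus on the forced pair, all alternative uses of
  # its endpoints blocked (pseudoknot-layer forced endpoints are blocked
  # from the primary layer entirely)
  BIG <- 1e6
  used <- unique(as.vector(forced))
  if (length(used)) {
    w[used, ] <- -1
    w[, used] <- -1
  }
  for (r in seq_len(NROW(primary_forced))) {
    i <- primary_forced[r, 1L]; j <- primary_forced[r, 2L]
    w[i, j] <- BIG + f_weight[f_layer == 1L][r]
  }

  dp <- cpp_nussinov(w, as.integer(min_loop))
  pairs <- cbind(i = dp$pair_i, j = dp$pair_j)
  layers <- rep(1L, NROW(pairs))
  if (NROW(forced)) {
    pk <- f_layer > 1L
    pairs <- rbind(pairs, forced[pk, , drop = FALSE])
    layers <- c(layers, f_layer[pk])
  }
  ord <- order(pairs[, 1L])
  pairs <- pairs[ord, , drop = FALSE]
  layers <- layers[ord]
  score <- dp$score - BIG * NROW(primary_forced)
  new_secondary_structure(pairs, layers, L,
                          score = if (L >= 2) score else 0)
}

new_secondary_structure <- function(pairs, layers, length, score = NA_real_) {
  colnames(pairs) <- c("i", "j")
  ss <- structure(list(pairs = pairs, layers = as.integer(layers),
                       length = as.integer(length), score = score),
                  class = "secondary_structure")
  ss$dotbracket <- render_dotbracket(ss)
  ss
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary structure: %d pairs over %d nt\n",
              NROW(x$pairs), x$length))
  cat(" ", x$dotbracket, "\n")
  invisible(x)
}

code_string <- function(s) {
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("U")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  if (!nchar(s)) return(integer(0))
  codes <- lut[utf8ToInt(s)]
  if (any(codes == 0L)) stop("consensus must be over A,C,G,U,N", call. = FALSE)
  codes
}

# weight matrix: 1 for eligible (WC/wobble, N wildcard, loop respected),
# -1 otherwise
eligibility_weights <- function(codes, min_loop) {
  L <- length(codes)
  w <- matrix(-1, L, L)
  if (L < 2L) return(w)
  can <- matrix(FALSE, 5L, 5L)
  can[1L, 4L] <- can[4L, 1L] <- TRUE   # A:U
  can[2L, 3L] <- can[3L, 2L] <- TRUE   # C:G
  can[3L, 4L] <- can[4L, 3L] <- TRUE   # G:U
  can[5L, ] <- can[, 5L] <- TRUE       # N wildcard
  for (i in seq_len(L - 1L)) {
    js <- seq_len(L)[-seq_len(min(i + min_loop, L))]
    for (j in js) if (can[codes[i], codes[j]]) w[i, j] <- 1
  }
  w
}

as_pair_matrix <- function(p) {
  if (is.null(p) || NROW(p) == 0L) {
    return(matrix(integer(0), 0L, 2L, dimnames = list(NULL, c("i", "j"))))
  }
  p <- as.matrix(p)[, 1:2, drop = FALSE]
  storage.mode(p) <- "integer"
  swap <- p[, 1L] > p[, 2L]
  p[swap, ] <- p[swap, 2:1]
  colnames(p) <- c("i", "j")
  p
}

# canonical/wobble (N wildcard) check on a consensus string, 1-based
pair_is_canonical <- function(consensus, i, j) {
  codes <- code_string(toupper(gsub("T", "U", consensus, fixed = TRUE)))
  a <- codes[i]; b <- codes[j]
  a == 5L || b == 5L ||
    (a == 1L && b == 4L) || (a == 4L && b == 1L) ||
    (a == 2L && b == 3L) || (a == 3L && b == 2L) ||
    (a == 3L && b == 4L) || (a == 4L && b == 3L)
}

check_forced <- function(forced, excluded, codes, min_loop) {
  if (!NROW(forced)) return(invisible(TRUE))
  pos <- as.vector(forced)
  if (anyDuplicated(pos)) {
    stop("conflicting forced pairs: a position is used twice", call. = FALSE)
  }
  if (any(pos < 1L | pos > length(codes))) {
    stop("forced pair position out of range", call. = FALSE)
  }
  can <- function(a, b) {
    a == 5L || b == 5L ||
      (a == 1L && b == 4L) || (a == 4L && b == 1L) ||
      (a == 2L && b == 3L) || (a == 3L && b == 2L) ||
      (a == 3L && b == 4L) || (a == 4L && b == 3L)
  }
  for (r in seq_len(nrow(forced))) {
    i <- forced[r, 1L]; j <- forced[r, 2L]
    if (!can(codes[i], codes[j])) {
      stop("forced pair (", i, ",", j, ") is not canonical/wobble in the ",
           "consensus", call. = FALSE)
    }
  }
  if (NROW(excluded)) {
    key_f <- paste(forced[, 1L], forced[, 2L])
    key_e <- paste(excluded[, 1L], excluded[, 2L])
    if (any(key_f %in% key_e)) {
      stop("a forced pair is also excluded", call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Greedy layering: pairs sorted by descending weight go to the lowest
# layer where they cross nothing already assigned.
assign_layers <- function(pairs, weight) {
  n <- NROW(pairs)
  if (!n) return(integer(0))
  ord <- order(-weight, pairs[, 1L])
  layer <- integer(n)
  layer_sets <- list()
  crosses <- function(p, set) {
    if (!NROW(set)) return(FALSE)
    i <- p[1L]; j <- p[2L]
    any((set[, 1L] < i & i < set[, 2L] & set[, 2L] < j) |
        (i < set[, 1L] & set[, 1L] < j & j < set[, 2L]))
  }
  for (r in ord) {
    p <- pairs[r, ]
    placed <- FALSE
    for (l in seq_along(layer_sets)) {
      if (!crosses(p, layer_sets[[l]])) {
        layer_sets[[l]] <- rbind(layer_sets[[l]], p)
        layer[r] <- l
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      layer_sets[[length(layer_sets) + 1L]] <- matrix(p, 1L)
      layer[r] <- length(layer_sets)
    }
  }
  layer
}

#' Decompose a structure into stems
#'
#' A stem (helix) is a maximal run of stacked pairs
#' `(i,j), (i+1,j-1), ...`. With `bulge_tol = k` a run may additionally
#' jump up to `k` unpaired positions on either strand between consecutive
#' members. Pseudoknot-layer pairs form their own stems.
#'
#' @param ss a `secondary_structure` (or two-column pair matrix).
#' @param bulge_tol bulge tolerance (default 0, strictest stacking).
#' @return list of two-column pair matrices, one per stem, each ordered by
#'   `i`.
#' @export
stems <- function(ss, bulge_tol = 0L) {
  pairs <- if (inherits(ss, "secondary_structure")) ss$pairs else
    as_pair_matrix(ss)
  layers <- if (inherits(ss, "secondary_structure")) ss$layers else
    rep(1L, NROW(pairs))
  if (!NROW(pairs)) return(list())
  ord <- order(layers, pairs[, 1L])
  pairs <- pairs[ord, , drop = FALSE]
  layers <- layers[ord]
  out <- list()
  cur <- pairs[1L, , drop = FALSE]
  for (r in seq_len(NROW(pairs))[-1L]) {
    prev <- cur[NROW(cur), ]
    p <- pairs[r, ]
    same_layer <- layers[r] == layers[r - 1L]
    di <- p[1L] - prev[1L] - 1L
    dj <- prev[2L] - p[2L] - 1L
    stacked <- di >= 0L && dj >= 0L && di <= bulge_tol && dj <= bulge_tol
    if (same_layer && stacked) {
      cur <- rbind(cur, p)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- matrix(p, 1L, dimnames = list(NULL, c("i", "j")))
    }
  }
  out[[length(out) + 1L]] <- cur
  out
}

#' Render a structure as dot-bracket text
#'
#' Primary-layer pairs as `()`, pseudoknot layers as `Aa`, `Bb`, ...;
#' unpaired positions as `.`.
#'
#' @param ss a `secondary_structure`, or a two-column pair matrix (then
#'   `length` is required).
#' @param length sequence length (taken from `ss` when absent).
#' @return character string.
#' @export
render_dotbracket <- function(ss, length = NULL) {
  if (inherits(ss, "secondary_structure")) {
    pairs <- ss$pairs; layers <- ss$layers
    if (is.null(length)) length <- ss$length
  } else {
    pairs <- as_pair_matrix(ss)
    layers <- rep(1L, NROW(pairs))
    if (is.null(length)) stop("length required", call. = FALSE)
  }
  if (NROW(pairs) && max(pairs) > length) {
    stop("pair position exceeds sequence length", call. = FALSE)
  }
  if (NROW(pairs) && max(layers) > 27L) {
    stop("more pseudoknot layers than rendering alphabet", call. = FALSE)
  }
  chars <- rep(".", length)
  for (r in seq_len(NROW(pairs))) {
    l <- layers[r]
    if (l == 1L) {
      chars[pairs[r, 1L]] <- "("
      chars[pairs[r, 2L]] <- ")"
    } else {
      chars[pairs[r, 1L]] <- LETTERS[l - 1L]
      chars[pairs[r, 2L]] <- letters[l - 1L]
    }
  }
  paste(chars, collapse = "")
}
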