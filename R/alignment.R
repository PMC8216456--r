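#' Construct an RNA multiple sequence alignment
#'
#' The central container of the package: an ordered set of equal-length
#' gapped RNA sequences with per-row identifiers, optional genome labels and
#' homology-search scores, and an optional consensus secondary structure
#' (WUSS/dot-bracket) covering the alignment columns.
#'
#' Sequences are uppercased on construction and DNA `T` is normalized to `U`.
#' The alphabet is restricted to `A`, `C`, `G`, `U` and the gap symbols `-`
#' and `.` (plus `N` for ambiguity); the two gap symbols are equivalent for
#' all counting operations. Coordinates are 1-based and inclusive throughout.
#'
#' @param seqs character vector of gapped sequences, all the same length.
#' @param seq_id character vector of row identifiers (default `seq1..seqN`).
#' @param genome_id character vector of genome labels, one per row. Defaults
#'   to everything before the first `/` of `seq_id`, the usual
#'   `genome/start-end` convention of homology-search output.
#' @param score numeric vector of per-row scores (e.g. nhmmer bit scores),
#'   `NA` where absent.
#' @param ss_cons optional consensus structure string, one character per
#'   alignment column, with balanced pairing symbols.
#' @return An object of class `rna_alignment`.
#' @examples
#' aln <- rna_alignment(c("GGGAAACCC", "GGCAAAGCC"), ss_cons = "<<<...>>>")
#' n_columns(aln)
#' @export
rna_alignment <- function(seqs, seq_id = NULL, genome_id = NULL,
                          score = NULL, ss_cons = NULL) {
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  n <- length(seqs)
  if (is.null(seq_id)) seq_id <- paste0("seq", seq_len(n))
  if (is.null(genome_id)) genome_id <- sub("/.*$", "", seq_id)
  if (is.null(score)) score <- rep(NA_real_, n)
  stopifnot(length(seq_id) == n, length(genome_id) == n, length(score) == n)
  ncol <- if (n > 0L) nchar(seqs[[1L]]) else 0L
  if (n > 0L && any(nchar(seqs) != ncol)) {
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  }
  bad <- grepl("[^ACGUN.-]", seqs)
  if (any(bad)) {
    stop("invalid residue in sequence '", seq_id[which(bad)[1L]],
         "': alphabet is A,C,G,U,N,-,.", call. = FALSE)
  }
  if (!is.null(ss_cons)) {
    if (nchar(ss_cons) != ncol) {
      stop("ss_cons length ", nchar(ss_cons),
           " does not match alignment width ", ncol, call. = FALSE)
    }
    check_balanced_ss(ss_cons)
  }
  structure(
    list(seq = seqs, seq_id = as.character(seq_id),
         genome_id = as.character(genome_id), score = as.numeric(score),
         n_columns = as.integer(ncol), ss_cons = ss_cons),
    class = "rna_alignment")
}

#' @export
print.rna_alignment <- function(x, ...) {
  cat(sprintf("RNA alignment: %d sequences x %d columns%s\n",
              n_rows(x), n_columns(x),
              if (!is.null(x$ss_cons)) " (with SS_cons)" else ""))
  show <- utils::head(seq_len(n_rows(x)), 6L)
  for (i in show) {
    s <- x$seq[[i]]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-20s %s\n", x$seq_id[[i]], s))
  }
  if (n_rows(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Alignment dimensions
#' @param aln an `rna_alignment`.
#' @return integer.
#' @export
n_rows <- function(aln) length(aln$seq)

#' @rdname n_rows
#' @export
n_columns <- function(aln) aln$n_columns

# Integer encoding used by all statistic kernels:
# gap ('-','.') = 0, A = 1, C = 2, G = 3, U = 4, N = 5.
aln_codes <- function(aln) {
  if (n_rows(aln) == 0L) return(matrix(integer(0), 0L, n_columns(aln)))
  m <- matrix(0L, n_rows(aln), n_columns(aln))
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("U")] <- 4L
  lut[utf8ToInt("N")] <- 5L
  for (i in seq_len(n_rows(aln))) {
    m[i, ] <- lut[utf8ToInt(aln$seq[[i]])]
  }
  m
}

codes_to_seq <- function(m) {
  alpha <- c("-", "A", "C", "G", "U", "N")
  apply(m, 1L, function(r) paste(alpha[r + 1L], collapse = ""))
}

# Pairing symbols we honour in SS_cons strings. WUSS annotation uses
# <>, (), [], {} for nesting plus Aa..Zz for pseudoknots.
ss_open  <- c("<", "(", "[", "{")
ss_close <- c(">", ")", "]", "}")

check_balanced_ss <- function(ss) {
  chars <- strsplit(ss, "", fixed = TRUE)[[1L]]
  for (k in seq_along(ss_open)) {
    depth <- cumsum((chars == ss_open[k]) - (chars == ss_close[k]))
    if (any(depth < 0L) || depth[length(depth)] != 0L) {
      stop("unbalanced consensus structure: symbol '", ss_open[k],
           "' does not nest", call. = FALSE)
    }
  }
  for (l in LETTERS) {
    if (sum(chars == l) != sum(chars == tolower(l))) {
      stop("unbalanced consensus structure: pseudoknot layer '", l, "'",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Extract the base pairs annotated in a structure string
#'
#' Accepts dot-bracket/WUSS text using `<>`, `()`, `[]`, `{}` for nested
#' pairs and `Aa`–`Zz` for pseudoknot layers. All other characters are
#' treated as unpaired.
#'
#' @param ss structure string.
#' @return two-column integer matrix of pairs `(i, j)`, `i < j`, 1-based.
#' @export
parse_structure <- function(ss) {
  chars <- strsplit(ss, "", fixed = TRUE)[[1L]]
  pairs <- matrix(integer(0), 0L, 2L)
  close_of <- function(op, cl) {
    stack <- integer(0)
    out <- matrix(integer(0), 0L, 2L)
    for (pos in seq_along(chars)) {
      if (chars[pos] == op) stack <- c(stack, pos)
      else if (chars[pos] == cl) {
        if (!length(stack)) stop("unbalanced '", cl, "' at column ", pos,
                                 call. = FALSE)
        out <- rbind(out, c(stack[length(stack)], pos))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack)) stop("unbalanced '", op, "'", call. = FALSE)
    out
  }
  for (k in seq_along(ss_open)) {
    pairs <- rbind(pairs, close_of(ss_open[k], ss_close[k]))
  }
  for (l in LETTERS) {
    if (any(chars == l)) pairs <- rbind(pairs, close_of(l, tolower(l)))
  }
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, 1L]), , drop = FALSE]
}
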