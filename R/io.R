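#' Read a Stockholm 1.0 alignment
#'
#' Parses single- or multi-block Stockholm, capturing sequence rows,
#' per-sequence scores from `#=GS <name> SC <value>` annotations, and the
#' consensus structure from `#=GC SS_cons`. Other annotation lines are
#' ignored. `T` is normalized to `U` and rows are uppercased.
#'
#' @param path file path.
#' @return an [rna_alignment].
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM 1\\.0", lines[[1L]])) {
    stop("not a Stockholm file (missing '# STOCKHOLM 1.0' header): ", path,
         call. = FALSE)
  }
  ids <- character(0)
  seqs <- list()
  ss <- character(0)
  scores <- list()
  for (ln in seq_along(lines)[-1L]) {
    line <- lines[[ln]]
    if (line == "" || line == "//") next
    if (startsWith(line, "#=GC SS_cons")) {
      part <- sub("^#=GC SS_cons\\s+", "", line)
      ss <- c(ss, part)
      next
    }
    if (startsWith(line, "#=GS")) {
      f <- strsplit(trimws(line), "\\s+")[[1L]]
      if (length(f) >= 4L && f[3L] == "SC") scores[[f[2L]]] <- as.numeric(f[4L])
      next
    }
    if (startsWith(line, "#")) next
    f <- strsplit(trimws(line), "\\s+")[[1L]]
    if (length(f) != 2L) {
      stop("malformed sequence line ", ln, " in ", path, call. = FALSE)
    }
    if (f[1L] %in% ids) {
      k <- match(f[1L], ids)
      seqs[[k]] <- paste0(seqs[[k]], f[2L])
    } else {
      ids <- c(ids, f[1L])
      seqs[[length(ids)]] <- f[2L]
    }
  }
  seqs <- unlist(seqs, use.names = FALSE)
  if (is.null(seqs)) seqs <- character(0)
  if (length(seqs) && length(unique(nchar(seqs))) > 1L) {
    stop("ragged rows in Stockholm file: ", path, call. = FALSE)
  }
  ss_cons <- if (length(ss)) paste(ss, collapse = "") else NULL
  sc <- rep(NA_real_, length(ids))
  if (length(scores)) sc[match(names(scores), ids)] <- unlist(scores)
  rna_alignment(seqs, seq_id = ids, score = sc, ss_cons = ss_cons)
}

#' Write a Stockholm 1.0 alignment
#'
#' Single-block output with `#=GS ... SC` score annotations for rows that
#' carry scores and `#=GC SS_cons` when a consensus structure is present.
#'
#' @param aln an [rna_alignment].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(aln, path) {
  wid <- max(12L, nchar(aln$seq_id), nchar("#=GC SS_cons"))
  out <- c("# STOCKHOLM 1.0", "")
  has_sc <- !is.na(aln$score)
  if (any(has_sc)) {
    out <- c(out, sprintf("#=GS %-*s SC %s", wid - 5L,
                          aln$seq_id[has_sc],
                          format(aln$score[has_sc], trim = TRUE)), "")
  }
  out <- c(out, sprintf("%-*s %s", wid, aln$seq_id, aln$seq))
  if (!is.null(aln$ss_cons)) {
    out <- c(out, sprintf("%-*s %s", wid, "#=GC SS_cons", aln$ss_cons))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Read / write ungapped sequences as FASTA
#'
#' Thin wrappers over Biostrings; `T` is normalized to `U` on read.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  stats::setNames(seqs, names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a region table
#'
#' Tab-separated table of genomic regions with 1-based inclusive
#' coordinates. Columns: `contig`, `start`, `end`, `strand`, `kind`,
#' `name`; lines starting with `#` are comments. `kind` is one of
#' `IGR`, `intron`, `five_prime_UTR`, `three_prime_UTR`, `CDS`.
#'
#' @param path file path.
#' @return data.frame with one row per region and a `length` column.
#' @export
read_region_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE,
                          col.names = c("contig", "start", "end",
                                        "strand", "kind", "name"))
  validate_regions(df)
  df$length <- df$end - df$start + 1L
  df
}

region <- function(contig, start, end, strand = "+", kind = "IGR",
                   name = NA_character_) {
  df <- data.frame(contig = contig, start = as.integer(start),
                   end = as.integer(end), strand = strand, kind = kind,
                   name = name, stringsAsFactors = FALSE)
  validate_regions(df)
  df$length <- df$end - df$start + 1L
  df
}

validate_regions <- function(df) {
  kinds <- c("IGR", "intron", "five_prime_UTR", "three_prime_UTR", "CDS")
  if (any(df$start < 1L | df$end < df$start)) {
    stop("invalid region coordinates: need 1 <= start <= end", call. = FALSE)
  }
  if (any(!df$strand %in% c("+", "-"))) {
    stop("region strand must be '+' or '-'", call. = FALSE)
  }
  if (any(!df$kind %in% kinds)) {
    stop("unknown region kind; expected one of ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
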