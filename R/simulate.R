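#' Specification for a simulated structured alignment
#'
#' Describes a star-tree simulation: one uniformly random ancestor whose
#' planted stems are forced complementary, from which every row is derived
#' independently. Each unconstrained site substitutes with probability
#' `per_site_sub_prob`; when a paired site substitutes, its partner is
#' switched to a complementary residue (Watson-Crick or wobble, chosen
#' uniformly) with probability `compensation_prob` — the compensatory
#' base-pair substitution process — and otherwise evolves independently.
#' Columns inside `conserved_spans` (e.g. H/ACA box motifs) never mutate.
#'
#' Independent rows make the column-permutation null exact for these
#' fixtures, which keeps calibration tests honest; a real phylogeny would
#' make the permutation null anti-conservative (see the vignette).
#'
#' @param n_seqs number of rows.
#' @param length alignment length (columns; the simulator emits no indels).
#' @param stems list of `c(i_start, j_start, stem_len)` triples: pairs
#'   `(i_start + k, j_start - k)` for `k = 0..stem_len-1`. Stems must fit
#'   inside the alignment, leave a hairpin loop of >= 3 positions, and not
#'   overlap.
#' @param per_site_sub_prob per-row, per-site substitution probability.
#' @param compensation_prob probability that a substitution at a paired
#'   site is compensated by its partner.
#' @param conserved_spans list of `c(first_col, last_col)` spans held
#'   fixed.
#' @param seed integer seed.
#' @return a `structured_aln_spec` list.
#' @export
structured_aln_spec <- function(n_seqs = 40L, length = 120L,
                                stems = list(c(20L, 60L, 6L)),
                                per_site_sub_prob = 0.3,
                                compensation_prob = 0.9,
                                conserved_spans = list(), seed = 1L) {
  spec <- list(n_seqs = as.integer(n_seqs), length = as.integer(length),
               stems = stems, per_site_sub_prob = per_site_sub_prob,
               compensation_prob = compensation_prob,
               conserved_spans = conserved_spans, seed = as.integer(seed))
  validate_structured_spec(spec)
  structure(spec, class = "structured_aln_spec")
}

validate_structured_spec <- function(spec) {
  stopifnot(spec$n_seqs >= 1L, spec$length >= 1L,
            spec$per_site_sub_prob >= 0, spec$per_site_sub_prob <= 1,
            spec$compensation_prob >= 0, spec$compensation_prob <= 1)
  used <- integer(0)
  for (st in spec$stems) {
    i0 <- st[1L]; j0 <- st[2L]; k <- st[3L]
    if (k < 1L || i0 < 1L || j0 > spec$length ||
        (i0 + k - 1L) + 3L >= (j0 - k + 1L)) {
      stop("invalid stem geometry: c(", paste(st, collapse = ","), ")",
           call. = FALSE)
    }
    pos <- c(i0:(i0 + k - 1L), (j0 - k + 1L):j0)
    if (any(pos %in% used)) stop("overlapping stems", call. = FALSE)
    used <- c(used, pos)
  }
  for (sp in spec$conserved_spans) {
    if (sp[1L] < 1L || sp[2L] > spec$length || sp[1L] > sp[2L]) {
      stop("conserved span out of range", call. = FALSE)
    }
  }
  invisible(TRUE)
}

stem_pairs <- function(stems) {
  do.call(rbind, c(list(matrix(integer(0), 0L, 2L)), lapply(stems, function(st) {
    k <- seq_len(st[3L]) - 1L
    cbind(st[1L] + k, st[2L] - k)
  })))
}

# complements including wobble: what can pair with code a
complement_set <- list(`1` = 4L, `2` = 3L, `3` = c(2L, 4L), `4` = c(1L, 3L))

#' Simulate an alignment with planted covarying stems
#'
#' @param spec a [structured_aln_spec()].
#' @return an [rna_alignment] carrying the planted structure in `ss_cons`.
#' @export
simulate_structured_alignment <- function(spec) {
  validate_structured_spec(spec)
  pairs <- stem_pairs(spec$stems)
  conserved <- unique(unlist(lapply(spec$conserved_spans,
                                    function(sp) sp[1L]:sp[2L])))
  with_local_seed(spec$seed, {
    L <- spec$length
    anc <- sample.int(4L, L, replace = TRUE)
    for (r in seq_len(NROW(pairs))) {
      comp <- complement_set[[anc[pairs[r, 1L]]]]
      anc[pairs[r, 2L]] <- comp[sample.int(length(comp), 1L)]
    }
    paired_pos <- as.vector(pairs)
    free_pos <- setdiff(seq_len(L), c(paired_pos, conserved))
    m <- matrix(0L, spec$n_seqs, L)
    mutate <- function(old) {
      cand <- setdiff(1:4, old)
      cand[sample.int(3L, 1L)]
    }
    for (s in seq_len(spec$n_seqs)) {
      row <- anc
      for (p in free_pos) {
        if (stats::runif(1L) < spec$per_site_sub_prob) row[p] <- mutate(row[p])
      }
      for (r in seq_len(NROW(pairs))) {
        i <- pairs[r, 1L]; j <- pairs[r, 2L]
        if (i %in% conserved || j %in% conserved) next
        # either side of the pair may substitute; a compensated
        # substitution switches the partner to a complementary residue
        if (stats::runif(1L) < spec$per_site_sub_prob) {
          row[i] <- mutate(row[i])
          if (stats::runif(1L) < spec$compensation_prob) {
            comp <- complement_set[[row[i]]]
            row[j] <- comp[sample.int(length(comp), 1L)]
            next
          }
        }
        if (stats::runif(1L) < spec$per_site_sub_prob) {
          row[j] <- mutate(row[j])
          if (stats::runif(1L) < spec$compensation_prob) {
            comp <- complement_set[[row[j]]]
            row[i] <- comp[sample.int(length(comp), 1L)]
          }
        }
      }
      m[s, ] <- row
    }
    ss <- render_dotbracket(pairs, length = L)
    rna_alignment(codes_to_seq(m),
                  seq_id = paste0("seq", seq_len(spec$n_seqs)),
                  genome_id = paste0("genome", seq_len(spec$n_seqs)),
                  ss_cons = ss)
  })
}

#' Simulate a structure-free control alignment
#'
#' Rows of i.i.d. uniform residues: no covariation, no conservation. The
#' null-model control for calibration tests — every column pair of such an
#' alignment is a true null, and the column-permutation null is exact.
#'
#' @param n_seqs number of rows.
#' @param length alignment length.
#' @param seed integer seed.
#' @return an [rna_alignment] without `ss_cons`.
#' @export
simulate_unstructured_alignment <- function(n_seqs = 30L, length = 80L,
                                            seed = 1L) {
  with_local_seed(seed, {
    m <- matrix(sample.int(4L, n_seqs * length, replace = TRUE),
                n_seqs, length)
    rna_alignment(codes_to_seq(m), seq_id = paste0("seq", seq_len(n_seqs)),
                  genome_id = paste0("genome", seq_len(n_seqs)))
  })
}

#' Specification for a codon-like coding alignment
#'
#' Emulates the covariation signature of unannotated protein-coding
#' sequence: for each codon, rows draw from a small set of codon variants
#' whose three positions co-vary. With probability `within_codon_corr` a
#' row takes an intact variant (all three positions jointly); otherwise
#' the three positions are drawn independently from the variant set's
#' marginals, breaking the within-codon association.
#'
#' @param n_seqs number of rows.
#' @param n_codons number of codons (alignment length is `3 * n_codons`).
#' @param within_codon_corr probability of drawing an intact codon variant.
#' @param seed integer seed.
#' @return a `coding_aln_spec` list.
#' @export
coding_aln_spec <- function(n_seqs = 50L, n_codons = 30L,
                            within_codon_corr = 0.9, seed = 1L) {
  stopifnot(within_codon_corr >= 0, within_codon_corr <= 1,
            n_seqs >= 1L, n_codons >= 1L)
  structure(list(n_seqs = as.integer(n_seqs), n_codons = as.integer(n_codons),
                 within_codon_corr = within_codon_corr,
                 seed = as.integer(seed)),
            class = "coding_aln_spec")
}

#' Simulate a codon-like coding alignment
#'
#' @param spec a [coding_aln_spec()].
#' @return an [rna_alignment] of length `3 * n_codons`, no `ss_cons`.
#' @export
simulate_coding_alignment <- function(spec) {
  with_local_seed(spec$seed, {
    n <- spec$n_seqs
    m <- matrix(0L, n, 3L * spec$n_codons)
    for (cdn in seq_len(spec$n_codons)) {
      # 4 variants; each position carries the 4 residues in its own
      # random order, so the variant index determines every position
      variants <- vapply(1:3, function(p) sample.int(4L), integer(4L))
      idx <- sample.int(4L, n, replace = TRUE)
      intact <- stats::runif(n) < spec$within_codon_corr
      cols <- 3L * (cdn - 1L) + 1:3
      for (p in 1:3) {
        drawn <- variants[sample.int(4L, n, replace = TRUE), p]
        m[, cols[p]] <- ifelse(intact, variants[idx, p], drawn)
      }
    }
    rna_alignment(codes_to_seq(m), seq_id = paste0("seq", seq_len(n)),
                  genome_id = paste0("genome", seq_len(n)))
  })
}

#' Generate a guide/target fixture with one planted pocket
#'
#' Draws a uniform-random RNA target, plants a uridine at an interior
#' position, and derives guide halves perfectly Watson-Crick
#' complementary to the `flank` nucleotides on each side of the pocket
#' (ψ and ψ+1 left unpaired). The construction is rejected and redrawn
#' (within the same seeded stream) until the guide matches the target at
#' exactly one position, so the fixture's pocket is unambiguous.
#'
#' @param seed integer seed.
#' @param target_len target length (default 120).
#' @param flank planted flank length per side (default 8).
#' @return list `guide5`, `guide3`, `target` (strings), `psi_pos`
#'   (planted ψ position).
#' @export
make_snorna_fixture <- function(seed, target_len = 120L, flank = 8L) {
  alpha <- c("A", "C", "G", "U")
  wc <- c(`1` = 4L, `2` = 3L, `3` = 2L, `4` = 1L)
  with_local_seed(seed, {
    repeat {
      tg <- sample.int(4L, target_len, replace = TRUE)
      t <- sample(seq.int(flank + 1L, target_len - flank - 1L), 1L)
      tg[t] <- 4L
      g3 <- wc[tg[t - seq_len(flank)]]                 # pairs t-1, t-2, ...
      down <- tg[t + 1L + seq_len(flank)]              # t+2, t+3, ...
      g5 <- rev(wc[down])                              # g5 read 3' -> 5'
      target <- paste(alpha[tg], collapse = "")
      guide5 <- paste(alpha[g5], collapse = "")
      guide3 <- paste(alpha[g3], collapse = "")
      hits <- guide_target_search(guide5, guide3, target, min_bp = 4L)
      if (nrow(hits) == 1L && hits$target_pos == t) {
        return(list(guide5 = guide5, guide3 = guide3, target = target,
                    psi_pos = as.integer(t)))
      }
    }
  })
}
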