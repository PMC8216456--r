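# covscreen

Covariation-based screening of multiple sequence alignments for
evolutionarily conserved RNA secondary structure.

Structural non-coding RNAs (snoRNAs, spliceosomal RNAs, structured
UTR/intron elements) preserve their base pairing across species through
compensatory base-pair substitutions. The resulting *covariation*
between alignment columns is the one evolutionary signal unique to
conserved RNA structure, and `covscreen` builds a complete desk-scale
decision pipeline around it, for anyone curating candidate structural
RNAs from comparative-genomics alignments:

* **Per-pair statistics** — a G-test of independence over the joint
  residue counts of each column pair,
  `G = 2 Σ_ab n_ab ln(n_ab N / (n_a n_b))`, computed on gap-free rows.
* **E-value calibration** — a column-permutation null (each column
  shuffled independently across rows: covariation destroyed, base
  composition and conservation preserved) pooled over `n_null`
  replicates, with a gamma tail fitted for extrapolation;
  `E = n_pairs · P_null(G' ≥ G)`.
* **Covariation-constrained folding** — a weighted Nussinov/CYK dynamic
  program over the consensus that forces significant pairs, prohibits
  "negative" pairs (power but no covariation) and assigns crossing
  constraints to pseudoknot layers.
* **Candidate classification** — *pass* requires ≥ 3 significant pairs
  (E ≤ 0.05) with ≥ 2 in the same stem; a pair with E < 1e-4 opens a
  *rescue* path; significant E-values are aggregated by Fisher's method
  (−2 Σ ln pᵢ against χ²₂ₙ) and a screen's expected false positives are
  `n_tests × threshold`. A codon filter flags alignments whose
  significant pairs sit 1–2 nt apart (within-codon covariation of
  unannotated coding sequence).
* **H/ACA snoRNA guide analysis** — H box (`ANANNA`) / ACA box
  detection, guide–target pseudouridylation-pocket search with G:U
  wobble (≥ 4 bp each side of the unpaired ψ), and shuffle-based false
  positive rates.
* **Screen geometry** — 1000-nt windowing with 500-nt overlap over
  intergenic regions (minimum 100 nt), UTR/CDS caps for the
  coding-flanked search mode, non-coding column extraction with the
  ≥ 50-residue row filter, top-hit-per-genome deduplication.
* **Seeded simulators** — alignments with planted compensatory stems,
  codon-like alignments, structure-free controls and guide/target
  fixtures, so the whole pipeline is testable offline.

## Worked example

```r
library(covscreen)

# an alignment with one planted 6-pair compensatory stem
aln <- simulate_structured_alignment(structured_aln_spec(seed = 8))
sc  <- scan_alignment(aln, screen_config(seed = 300))
sc$verdict
#> candidate verdict: PASS (6 significant pairs, 6 in best stem; aggregated P = 1.09e-27)

# its column-shuffled twin: covariation destroyed, composition kept
twin <- shuffle_columns(aln, seed = 77)
scan_alignment(twin, screen_config(seed = 300))$verdict
#> candidate verdict: FAIL (0 significant pairs, 0 in best stem)

# Fisher aggregation of three covariation E-values, and the screen-level
# false-positive accounting for 134,000 tested alignments
fisher_aggregate(c(6.5e-7, 0.0053, 0.0204))
#> [1] 2.091875e-08
expected_false_positives(134000, 2.091875e-08)
#> [1] 0.002803113

# H/ACA guide-target search on a fixture with one planted pocket
fx <- make_snorna_fixture(3)
guide_target_search(fx$guide5, fx$guide3, fx$target)
#>     target_pos left_bp right_bp n_wobble
#> pos         12       8        8        0
```

The verdict means the alignment shows six column pairs whose
covariation exceeds everything seen in 25 column-shuffled nulls (E ≤
0.05), all six stacked in a single helix — comfortably beyond the
pass criteria — while the shuffled twin shows none. The guide search
reports one pseudouridylation pocket: ψ at target position 12 with 8
Watson–Crick pairs on each flank.

A command-line front end wrapping the same functions is installed as
`exec/covscreen` (subcommands `scan`, `simulate`, `aggregate`,
`snorna-target`, `fold`, `window`).

## Scope

The package consumes ready-made Stockholm alignments; iterative
homology search (nhmmer/Infernal), database construction and
phylogenetically aware null models are out of scope. The permutation
null is exact for independently evolving rows and anti-conservative for
deeply structured phylogenies — see the methods vignette
(`vignettes/conserved-structure-screening.Rmd`) for the model,
parameter defaults and limitations.
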