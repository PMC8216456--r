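---
title: "Screening alignments for conserved RNA structure with covscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening alignments for conserved RNA structure with covscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covscreen)
```

## The problem

Functional non-coding RNAs — snoRNAs, spliceosomal RNAs, riboswitch-like
*cis*-regulatory elements — tend to conserve their base-paired secondary
structure even as their primary sequence drifts. The diagnostic
evolutionary signature is the compensatory base-pair substitution: two
positions change together so that Watson–Crick or G:U wobble pairing is
preserved. In a multiple sequence alignment this shows up as
*covariation* between the two columns, and covariation is the only
evolutionary signal unique to structural RNA; primary conservation and
mere consistency-with-a-structure are shared with coding sequence and
protein-binding DNA, which is why screens built on them over-call.

covscreen implements a desk-scale version of a covariation-first screen:
score all column pairs, calibrate per-pair E-values against a
permutation null, fold the consensus under covariation constraints, and
accept an alignment as a structural-RNA candidate only when the
covariation evidence meets stem-aware criteria. Companion modules cover
H/ACA snoRNA guide–target analysis and the region geometry of a genome
screen (windowing, flanked-mode caps).

## Per-pair statistic and its null

For columns $i, j$, the package uses the G-test of independence over the
$4 \times 4$ joint residue counts on rows where neither position is a
gap:

$$G_{ij} = 2 \sum_{a,b} n_{ab} \ln \frac{n_{ab}\, N}{n_a\, n_b},$$

with empty cells contributing zero. $G = 0$ exactly when the joint
counts factorize; correlated compensatory substitutions push it up, and
it is invariant under row permutation. Rows with a gap at either
position are excluded rather than treated as a fifth symbol: gaps carry
alignment uncertainty, not substitution signal.

Significance is calibrated per alignment by a **column-permutation
null**: each column's contents are shuffled independently across rows,
which destroys inter-column covariation while preserving per-column base
composition and conservation exactly. `calibrate_null()` pools the pair
statistics of `n_null` such shuffled alignments, and
`pair_evalue()` converts a statistic into the expected number of pairs
at or above it per alignment,

$$E = n_\text{pairs} \cdot \hat P_\text{null}(G' \ge G),$$

using the empirical survival function with an add-one correction. A
pair is *significant* at the default $E \le 0.05$: fewer than 0.05
false base pairs are expected per alignment.

Two numerical details matter:

* **Resolution.** The smallest attainable E-value under the add-one
  rule is $n_\text{pairs} / (N_\text{null} + 1)$ with
  $N_\text{null} = n_\text{null} \cdot n_\text{pairs}$. The default
  `n_null = 25` therefore makes $E \le 0.05$ reachable
  ($25 > 1/0.05 - 1$ shuffles suffice for any alignment width), with
  headroom for ties.
* **Tail extrapolation.** Statistics beyond the largest pooled null
  value use a gamma tail fitted by method of moments to the exceedances
  over the 95% null quantile (location at the threshold), capped by the
  add-one bound. Without it, a finite null truncates E-values and the
  extreme-pair rescue path (below) would be unreachable.

The permutation null is exact when rows evolve independently — which is
how the packaged simulators generate data (a "star tree"), keeping the
calibration tests honest. For real alignments with deep phylogenetic
structure, shared ancestry itself induces covariation, and the
permutation null is anti-conservative relative to a tree-aware null.
This is a documented limitation; `null_calibration(stats = ...)`
accepts externally computed null statistics so a tree-aware simulator
can be plugged in without touching the rest of the pipeline.

**Power.** An alignment can lack covariation either because there is no
conserved structure or because there is no variation. The package uses
a substitution-count proxy: a column's substitution count is the number
of gap-free rows differing from its majority residue, and a pair *has
power* when both columns show at least `s_min = 2` substitutions. A
*negative pair* has power but no significant covariation — active
evidence against a conserved base pair — and is excluded from the
proposed structure. Rfam-calibrated power curves are out of scope; the
threshold is configurable.

## Constrained folding and stems

`constrained_fold()` is a weighted Nussinov/CYK dynamic program over
the alignment's consensus sequence (majority residue per column; `N`
where no residue reaches 50%; columns more than half gaps are dropped,
mirroring the usual display convention). Eligible pairs are
Watson–Crick or wobble with `N` as a wildcard; hairpin loops span at
least `min_loop = 3` positions. Every pair scores 1, significant pairs
score `1 + w_cov` (default 11), significant pairs are *forced* into the
structure, and negative pairs are *prohibited*. Forced pairs that
cannot all nest are assigned greedily by descending weight to
pseudoknot layers so that no significant pair is silently dropped. The
scoring is deliberately not thermodynamic: the fold's job is to
organize covarying pairs into stems for the decision criteria, not to
predict minimum free energy. The full cascade of alternative helices
used by covariation-constrained folding at database scale is out of
scope here.

`stems()` partitions pairs into maximal stacking runs
$(i,j), (i+1,j-1), \dots$. The stem boundary convention behind "same
stem" is not uniquely defined in the field — helices may or may not
absorb small bulges — so the bulge tolerance is exposed as
`bulge_tol` (default 0, the strictest reading) rather than fixed.

## Candidate criteria, rescue, aggregation

`classify()` calls an alignment a candidate (**pass**) when

1. at least `min_sig = 3` pairs are significant at $E \le 0.05$, and
2. at least `min_same_stem = 2` of them lie in the same stem of the
   proposed structure.

Alignments failing both criteria but containing a pair with
$E < 10^{-4}$ — over two orders of magnitude beyond the default
threshold — get a **rescue** verdict: primary-sequence alignments can
be structurally misaligned, and such an extreme pair warrants a
structure-informed second look. In this package the second look is a
re-fold with the rescuing pair forced; a verdict can never be upgraded
to pass by forcing, it only refines the proposed structure. At database
scale the analogous step is a covariance-model re-search.

Significant pairs' E-values are aggregated by Fisher's method:
$-2\sum_i \ln p_i$ against the $\chi^2_{2n}$ survival function. The
E-values are treated as P-values here, clamped to 1 where they exceed
it (the clamp count is recorded). For the reference worked example —
three covariations at $6.5\times10^{-7}$, $0.0053$, $0.0204$ —
`fisher_aggregate()` returns $2.1\times10^{-8}$, and a screen of
134,000 alignments at that threshold expects
$134{,}000 \times 2.1\times10^{-8} \approx 0.003$ false positives
(`expected_false_positives()`). The total number of alignments tested
in a screen is an input to this accounting, not something the package
can derive.

**Codon filter.** Unannotated coding sequence produces covariation
between positions one or two nucleotides apart (within-codon
interactions). `codon_covariation_filter()` counts significant pairs at
consensus-position distance 1–2 and flags the alignment when more than
3 occur. Distance is measured on ungapped consensus positions rather
than raw columns so gap columns cannot dilute the signal.

## Screen geometry

`window_region()` cuts regions longer than 1000 nt into 1000-nt windows
at a uniform 500-nt stride, with a final window ending at the region
end so every position is covered (a 2500-nt region gives four windows).
Regions under 100 nt are skipped: shorter queries cannot reach the
homology-search E-value threshold even as perfect matches. The printed
example coordinates for a 2500-nt region in the method's original
description imply an irregular stride for the last window; the package
implements the uniform stride with a remainder-covering final window,
which yields the same window count and full coverage.

For the flanked mode (introns/UTRs anchored by adjacent coding
sequence), `prepare_flanked_query()` caps the UTR at the 2000 nt
nearest the CDS junction and the flanking CDS at 1000 nt;
`extract_noncoding_span()` later slices the non-coding columns back out
of the first-round alignment, keeping rows with at least 50 non-gap
residues there (every non-gap symbol counts, ambiguous residues
included). `dedup_best_per_genome()` keeps the top-scoring hit per
genome — pseudogenes are no longer structurally constrained and dilute
covariation — breaking ties toward the earlier row for determinism.
Iterative homology search itself (and any external search binaries) is
out of scope; the package consumes ready-made Stockholm alignments and
records the E-value schedule of the canonical three-iteration search
($10^{-10}, 10^{-10}, 10^{-5}$) as configuration metadata.

## H/ACA guide–target search

`find_boxes()` locates the H box (`ANANNA`, last match before the
3'-terminal region) and the ACA box (ending within the last 5 nt).
`guide_target_search()` scans every uridine of a target rRNA as a
candidate pseudouridylation site ψ, requiring at least 4 consecutive
WC/wobble pairs on each side of the pocket with ψ and ψ+1 unpaired: the
3' guide half pairs the target upstream of ψ and the 5' half pairs
downstream of ψ+1, the canonical pocket geometry. The source method
states only the 4-bp-both-sides rule; the pocket geometry and the
requirement that the runs be consecutive (no internal mismatches) are
fixed here and documented. `N` in a guide breaks a run. The false
positive rate of a match is estimated by mononucleotide
(composition-preserving) shuffling of the target
(`fpr_by_shuffle()`): the fraction of shuffles containing a pocket
with at least as many total base pairs and no more wobbles. A
dinucleotide-preserving shuffle is available but off by default, since
the mononucleotide shuffle is the reference negative-control
construction.

## The simulators, and what passing tests do not show

`simulate_structured_alignment()` draws one uniform ancestor, forces
planted stems complementary, and mutates rows independently; a
substitution at a paired site is compensated (partner switched to a
complementary residue, wobble included) with probability
`compensation_prob`. Defaults — 40 rows, 120 columns, one 6-pair stem,
substitution probability 0.3, compensation 0.9 — represent a moderately
diverged alignment with a clearly conserved stem.
`simulate_coding_alignment()` emulates within-codon covariation;
`simulate_unstructured_alignment()` gives i.i.d. structure-free
controls; `make_snorna_fixture()` plants a single unambiguous
pseudouridylation pocket in a random target.

These fixtures deliberately lack indels, realistic phylogeny (rows are
independent), base-composition bias and codon-usage structure. Passing
the packaged tests therefore demonstrates that the statistics,
calibration and decision logic behave as specified under their own
model — not that real screens of real genomes will achieve any
particular sensitivity. Database-scale quantities (positive-control
detection rates, candidate counts, rRNA-target FPRs of real snoRNAs)
require genome databases and are explicitly not reproduced at desk
scale.

## Problem sizes used by the packaged checks

The test suite exercises: fold optimality against exhaustive
enumeration on 200 random sequences of length ≤ 12; E-value calibration
on 500 structure-free 30×80 alignments (mean significant pairs per
alignment expected in [0.02, 0.10] at the default `n_null = 25`; the
theoretical value under the add-one rule is
$\approx n_\text{pairs}/(N_\text{null}+1) = 0.04$); planted-stem
recovery on 100 simulator replicates (≥ 90 must pass; their
column-shuffled twins must never pass, matching a 0% negative-control
rate); and pocket recovery on 100 guide/target fixtures. The
acceptance script (`scripts/acceptance.R`) recomputes the same
quantities at somewhat smaller replicate counts chosen to keep a
single-CPU run short.

## Degenerate inputs and tie-breaks

Empty extraction results return 0-row alignments, not errors; consensus
ties break alphabetically (A < C < G < U); dedup ties keep the earlier
row; single-row alignments shuffle to themselves; an alignment with
fewer than two usable rows at a pair scores $G = 0$; forced-pair
conflicts (shared positions, forced-and-excluded) are errors, while
significant pairs that cannot form a canonical consensus pair are
simply not forced into the fold (they still count toward criterion
(i)). All coordinates are 1-based inclusive throughout; conversion to
other conventions is confined to format parsers.
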