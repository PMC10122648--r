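---
title: "Methods: TFBS orientation and order grammar analysis for MPRA libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TFBS orientation and order grammar analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbsgrammar)
```

## The scientific problem

Whether enhancers and promoters follow a rigid "enhanceosome" grammar or a
flexible "billboard" grammar hinges on how much the *orientation*, *order*,
*copy number* and *position* of transcription factor binding sites (TFBS)
matter, beyond their mere presence. Massively parallel reporter assays
(MPRA) let one ask this question systematically: thousands of designed
200-bp tiles, each carrying a controlled arrangement of TFBS kmers on a
neutral background, drive a barcoded reporter, and activity is read out as
the normalized RNA/DNA barcode ratio. This package implements the full
desk-side arm of such a study: combinatorial library design, a synthetic
data generator with planted grammar effects, activity quantification, the
statistics battery for grammar effects, genomic corroboration scans, and
strand-aware predictive modelling.

Throughout, a site on a tile is **non-template (NT)** when the kmer is
written on the tile's forward strand — the strand read 5'→3' toward the
minimal promoter at the tile's right end — and **template (T)** when its
reverse complement is. The convention (which strand the kmer string refers
to) is a genuine free choice; it is fixed here once and used consistently
by the designer, the simulator, the statistics and the feature encoding.
Palindromic kmers (in the bundled roster, only CREB1's TGACGTCA) carry no
orientation information and act as negative controls. All coordinates are
0-based half-open.

## Library design

`generate_library()` enumerates, per background:

* **homotypic** tiles: every motif × copy number {1,2,3,4,5,6,8} ×
  orientation vector × spacing rule. Orientation vectors are enumerated
  exhaustively (2^n) up to 6 copies; at 8 copies only all-NT, all-T and the
  two alternating vectors are built, a deliberate library-size control
  since the full 256-vector sweep adds little to the orientation contrasts
  the statistics use.
* **position sweep** tiles: one motif per tile in both orientations, one
  placement per 40-bp bin, so positions cover [−200, 0) relative to the
  TSS-proximal end.
* **pair** tiles: all ordered heterotypic pairs (306 for 18 motifs) × 4
  orientation vectors × spacing rules, optionally with 1–3 copies per
  member.
* **triplet** tiles: all ordered triplets (4,896 for 18 motifs) × 8
  orientation vectors, at the genomic-mode spacing only (the fixed-spacing
  sweep would multiply an already large category by 3).

Spacing between consecutive sites is the **edge-to-edge gap** in bp: fixed
5 bp, fixed 10 bp, or the "most frequent genomic distance".
`most_frequent_pair_distance()` computes the latter as the modal
start-to-start distance of two occurrence tracks within a 200-bp window
(ties to the smaller distance, documented fallback of 10 bp when no pair is
in range); start-to-start modes are converted to gaps by subtracting the
kmer length, floored at 0. Multi-site blocks are right-anchored
(promoter-proximal) by default because position relative to the TSS itself
carries signal; centered and left anchoring are configurable. Infeasible
configurations (block longer than the background) are skipped and recorded,
not fatal. The whole design is deterministic: identical configuration gives
a byte-identical design table.

The bundled roster (`grammar_motifs()`) carries the two literature
consensus kmers (AP1 TGACTCA, CREB1 TGACGTCA) and sixteen deterministic
synthetic stand-in kmers under the remaining real factor names, so the
combinatorics and statistics can be exercised without motif-database
downloads; they are labelled `synthetic` in their `source_id`.

## The synthetic-data generator

`simulate_counts()` is the package's study stand-in, not a fixture: a
tile's log2 activity is

    a = mu_bg + Σ beta(motif, orientation) · copies^dose_exponent
             + Σ position_slope · (position + 100)/100
             + Σ pair_interaction(A before B)

with `mu_bg` the background baseline (the second background sits 0.5 log2
units below the first, mirroring the weaker of the two assay backgrounds),
a saturating power-law dose response (exponent 0.5 by default, since
copy-number effects in reporter data are monotone but bounded), and ordered
pair interactions over first occurrences. Counts are negative binomial:
each tile receives a zero-truncated Poisson(50) number of barcodes and
three replicates; per barcode, DNA is NB around the depth share and RNA is
NB around `dna_mean · 2^(a + ε)`, where ε is a tile-by-replicate Gaussian
with sd `noise_sd`. Expected normalized log2(RNA/DNA) is therefore affine
in `a` with slope 1 (checked by regression in the tests).

`noise_sd` defaults to 0.55. That value was set once against the
replicate-concordance target the assay literature reports (between-replicate
Pearson r in the low-to-mid 0.7s to low 0.8s for large libraries): with the
default effect spread, per-replicate noise of 0.55 log2 units puts the
simulated homotypic library's replicate r at ≈0.75 (three-copy subset) to
≈0.83 (full copy sweep).

`simulate_promoter_set()` plants grammar into sequence space instead:
first-order Markov background (dinucleotide-controlled), one consecutive
homotypic pair per promoter whose second member matches the first's
orientation with probability `p_same`, and one heterotypic pair whose
designated member is TSS-proximal with probability `p_proximal`. The two
planted pairs live in separate promoter halves with a ≥140-bp buffer so
they cannot form spurious "consecutive" pairs at the default 100-bp gap.
A note on the background model: dinucleotide frequencies determine a
first-order chain, which is what is implemented; it is the same
composition control the Euler-path shuffle preserves.

What the generator does **not** emulate: PCR/UMI artifacts, barcode
dropout, viral-integration position effects, motif degeneracy (sites are
exact kmers), or chromatin context. Passing recovery tests therefore
demonstrates the statistics are correct and well calibrated under the
stated model — not that real MPRA data meet that model.

## Quantification

Following standard MPRA practice the filter is two-staged and the wording
"barcode counts lower than 3" is deliberately implemented both ways:
barcodes with DNA count < 3 are removed (boundary retained), then
tile-replicates with fewer than 3 surviving barcodes are dropped; both
floors are independently configurable. Expression is
`log2((rna/rna_total)/(dna/dna_total))` with per-replicate totals;
zero-RNA barcodes get a pseudocount of 1 on both counts. Tiles are
aggregated by the mean over barcodes, then the mean over surviving
replicates (mean, not median, matching the common MPRA pipeline default).
Backgrounds are kept separate and combined only on request, since their
baselines differ.

## The statistics battery

* **Orientation asymmetry** (`orientation_asymmetry_test()`): two-sided
  two-sample t-test, Student's by default (Welch by flag — variance
  heterogeneity between orientations is itself one of the findings the
  Levene test screens for). Effects are reported both as the ratio of
  group means on the linear activity scale (`mean(2^x)`), so "21% higher"
  statements are well defined, and as the log2 difference of means.
* **Copy-number and position trends**: Spearman correlation; the position
  statistic also reports the percent change of the mean linear activity in
  the [−40, 0) bin relative to [−200, −160).
* **Variance difference**: Brown–Forsythe/Levene (median-centered).
* **Order effects** and **configuration ANOVA**: the same t-test machinery
  keyed by order, and one-way ANOVA over the 4 pair / 8 triplet
  orientation configurations or 3 triplet slots.
* **Monte-Carlo gain test** (`monte_carlo_gain_test()`): observed statistic
  `|mean(NT4)−mean(T4)| − |mean(NT1)−mean(T1)|`; the null permutes
  orientation labels *within* each copy-number stratum (so copy-number
  main effects cannot leak into the null), one-sided
  `p = (1 + #{null ≥ obs}) / (1 + n_perm)`, seeded.
* **Multiplicity**: Bonferroni throughout, with the family size recorded
  per analysis family (18 motifs, 306 pairs, 4,896 triplets) and allowed to
  exceed the number of tests actually computed.

Calibration is part of the test suite: at 10,000 null replicates the
empirical type-I error of the t, binomial, ANOVA and Monte-Carlo tests is
required to sit within ±0.02 of α = 0.05, and a planted orientation
difference of 0.3 log2 units must be recovered with |bias| < 0.03
(estimated over 20 independent simulation runs of 200 tiles per group).

## Genomic corroboration

`pfm_to_pwm()` builds log2-odds matrices from JASPAR-style PFMs
(`read_meme()` parses MEME minimal format). `score_threshold()` computes
the exact score distribution under the background model by dynamic
programming over scores discretized to 10⁻³ log2 units and returns the
smallest score with tail probability ≤ p (default 10⁻⁴, the conventional
scanning stringency); the PWM matrix itself is discretized to the same
grid so the scanner and the threshold share one exact score scale, and the
DP is verified against exhaustive enumeration up to width 8. When the
discrete distribution cannot reach p the maximum score is returned and
flagged rather than silently extrapolated. `scan_sequence()` scores both
strands (reverse strand via the reverse-complemented matrix), reports
forward-strand coordinates, and skips windows containing N.

`extract_promoters()` takes the `upstream` bp ending at the gene start,
strand-aware and reverse-complemented for minus-strand genes so every
promoter reads toward its TSS. `consecutive_homotypic_asymmetry()`
implements the strand-asymmetry statistic S = n_same/(n_same+n_opposite)
over adjacent same-motif occurrences with edge-to-edge gap < 100 bp
(50 bp available as a stricter preset — both windows appear in the
literature), with exact two-sided binomial inference; overlapping
occurrences are merged to the higher-scoring one first.
`dinucleotide_shuffle()` is the Altschul–Erickson Euler-path shuffle,
preserving the dinucleotide multiset exactly, for composition-controlled
nulls. `pair_order_preference()` and `ccre_pair_enrichment()` complete the
genomic side: exact binomial tests of TSS-proximal preference, and
fractions of close pairs overlapping labelled element classes.

## Predictive modelling

`featurize()` encodes each tile as motif counts (18 strand-agnostic
columns) or motif-by-orientation counts (36 strand-aware columns; the
aware matrix summed over orientation reproduces the agnostic one, an
identity the tests assert). `fit_lasso_cv()` runs 10-fold outer
cross-validation with the L1 penalty chosen by inner cross-validation on
each training split (the penalty-selection rule is a free choice; nested
CV avoids optimistic pooled correlations), standardized features, an
unpenalized intercept, and an optional unpenalized background indicator
for models pooled over backgrounds with unequal baselines. Held-out
predictions are concatenated across folds for the pooled Pearson r and
Spearman rho; per-fold values are reported on both scales since either
convention appears in practice. `compare_models()` gives
`100·(r_aware − r_agnostic)/r_agnostic` on identical folds, and refuses
mismatched fold assignments.

The qualitative contract, enforced in the acceptance tests: when planted
orientation effects are antagonistic (β_NT = −β_T) the strand-aware model
dominates in ≥95% of seeded runs; when effects are orientation-symmetric
it shows no systematic advantage.

## Numerical choices and degenerate inputs

* Ties in the modal-distance search break toward the smaller distance;
  empty tracks fall back to 10 bp with a warning flag.
* Spearman/Kendall tests use the usual tie-corrected statistics; constant
  inputs are flagged `degenerate` rather than erroring.
* ANOVA groups with n < 2 are dropped with a warning; an all-constant
  response is reported with F = 0 and `degenerate = TRUE`.
* The threshold DP uses a 10⁻³ granularity; at width w the induced score
  error is ≤ w/2 · 10⁻³ log2 units, absorbed by scoring on the same grid.
* Skew statistics define 0/0 as 0 (a palindrome has both skews 0).
* RNG state: seeded helpers (`markov_from_seed()`, seeded shuffles,
  deterministic rosters) save and restore the caller's `.Random.seed`.

## Problem sizes

The shipped tests and the acceptance script run the full combinatorial
enumerations (306 pairs, 4,896 triplets) but simulate counts for focused
subsets — a few hundred to a few thousand tiles at ~50 barcodes × 3
replicates — which is ample for the calibration and recovery guarantees
above while keeping a complete run in minutes on one core. Scaling the
same calls to the full 200k-tile design is a matter of configuration, not
code.

## Known limitations

Sites are exact kmers (no affinity gradations); the designer does not
model synthesis adapters or barcode assignment; the genomic module scans
user-supplied sequences but does not download or version motif or
annotation resources; and the simulator's independence assumptions
(independent barcodes, Gaussian tile noise) are idealizations, so effect
sizes estimated from real data should be expected to be noisier than the
planted-recovery results suggest.
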