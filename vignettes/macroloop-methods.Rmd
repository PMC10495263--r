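---
title: "Linking chromatin domains, differential enhancers and promoter loops: methods"
author: "macroloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking chromatin domains, differential enhancers and promoter loops: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroloop)
```

## The analysis

`macroloop` reimplements, as a tested pipeline, an integrative
chromatin-architecture analysis for a two-genotype comparison (wild type
versus a macroH2A double knockout, "WT" / "dKO") in cultured fibroblasts:

1. **MacroH2A chromatin domains (MCDs).** Domain-level peak calls from all
   conditions are pooled and merged when within 25 kb. Domains are scored
   against the coverage track (signal x covered bp), ranked by
   size-normalized signal (density), and partitioned by a ROSE-style
   ranked-curve elbow into *super* domains, with the remainder split at a
   density-times-length cutoff of 3,780 into *standard* and *low* domains.
   Low domains (typically sub-1.5-kb, a negligible genome fraction) are
   flagged and excluded downstream rather than deleted, so reports can
   state the excluded fraction.
2. **Differential enhancers.** H3K27ac peaks from the master peak set are
   stitched at 12.5 kb with a 2.5 kb TSS exclusion zone (a peak is removed
   only when fully contained in the zone). Elements are quantified per
   sample, split into super-enhancers and traditional enhancers by the
   elbow of raw total signal, normalized across samples by each sample's
   mean over all elements (post-normalization column means are exactly 1),
   and classified gain / loss / static at a log2 fold change of +-0.75
   (inclusive; the static band is the open interval).
3. **Gene classification and matched controls.** Genes are classified up /
   down / static at adjusted p < 0.05 and |log2FC| > 0.75. For profile
   comparisons, expression-matched static controls are drawn per DE gene
   from genes within 25% of its WT TPM, at least 1 kb long, without
   replacement, de-duplicated keeping first occurrence, deterministically
   under a seed.
4. **Loop comparison.** Promoter-anchored loops (bait = promoter-side bin,
   10 kb bins) are retained at score >= 5 per condition. At fixed binning,
   "both ends overlap" reduces to exact (bait, distal) bin equality, which
   defines shared versus condition-unique loops. The fraction of unique
   loops explained by a +-1-bin distal shift is computed by greedy
   one-to-one matching over loops sorted by (chromosome, bait, distal).
   Loop counts are summed per gene over all baits mapped to it.
5. **Stratified association tests.** Chi-square tests of independence
   (no continuity correction) with Pearson residuals `(O - E) / sqrt(E)`,
   computed per macroH2A stratum (super / standard / none) for
   (i) enhancer status x loop relation and (ii) DE status x net loop
   change, with Holm adjustment across strata. Enhancers touched by loops
   of several classes vote once with precedence
   `unique_dKO > unique_WT > shared-only`; enhancers with no loops carry
   no loop information and are excluded. Degenerate strata (fewer than two
   non-empty rows or columns) are skipped with a note rather than tested.
6. **Target intersection.** A target gene is upregulated and has at least
   one retained loop, in either condition, from one of its baits to an
   enhancer that gained H3K27ac. The either-condition reading is
   deliberate: a promoter that merely keeps its contact with a
   hyperacetylated enhancer still has that enhancer as a plausible driver.
   Net loop gain is reported as a flag, as is membership of an optional
   user-supplied pathway list. A companion proximity analysis reports the
   distance from each gene body to the nearest gaining enhancer and flags
   genes within 50 kb.
7. **Profiles.** Metagene (scaled gene body plus fixed-width flanks,
   minus-strand genes mirrored) and point-centered average signal
   profiles, with percentile-bootstrap 95% confidence bands over regions;
   and genome-binned Pearson correlation between two coverage tracks.

## Numerical choices

- **Coordinates.** All on-disk formats are BED-convention 0-based
  half-open; in memory the package uses `GRanges` (1-based closed), with
  conversion confined to the readers and writers.
- **Merging.** Two intervals merge when the 0-based gap between them is at
  most the merge distance; touching intervals always merge.
- **Elbow.** Both axes of the ascending rank/value curve are scaled to
  [0, 1]; the cutoff is where the curve's slope reaches 1 coming from the
  steep end, located numerically as the point of maximum distance below
  the unit diagonal (the tangency condition in a form robust to
  rank-local noise; finite-difference slope scanning breaks as soon as two
  adjacent high-rank values are nearly equal). Ties take the rightmost
  point, so a perfectly linear ramp yields an empty super set
  (conservative calls). All-equal input has no elbow and nothing is
  called super.
- **Low-domain cutoff.** The 3,780 density-times-length rule is applied to
  non-super domains only; the elbow takes precedence.
- **Differential enhancers.** Replicates are averaged after per-sample
  normalization (normalization removes depth effects first). The
  fold-change pseudocount defaults to 1% of the global normalized mean, a
  scale-stable guard against zero denominators.
- **Chi-square.** Expected counts of zero raise an error instructing
  row/column collapse; sparse strata should be collapsed or skipped, not
  tested. Pearson residuals (not standardized residuals) are the reported
  heatmap quantity.
- **Holm adjustment** is the default across strata: valid without
  independence assumptions between the stratified tables.
- **Bootstrap.** Percentile bootstrap (2.5/97.5) with 1,000 resamples by
  default; a single region collapses the band onto its own profile.
  Uncovered bases contribute signal 0 (coverage semantics), not missing.
- **Greedy shift matching** prefers the lower distal partner when both
  neighbours are free, and never consumes a partner twice.

## The synthetic-data generator

`generate_dataset()` emits a complete desk-scale dataset — gene table,
domain peaks + signal track, H3K27ac peaks + four per-sample tracks
(2 conditions x 2 replicates), per-condition loop tables, bait-to-gene
map — together with a machine-readable truth record, byte-identically
reproducible under a seed. Defaults: one 50-Mb chromosome, 2,000 genes,
3,000 enhancers, 30 super (100-500 kb) / 300 standard (5-50 kb) / 100 low
(0.5-1.5 kb) domains, 5% up- and 5% down-regulated genes with |log2FC| ~
N(1.5, 0.3) truncated above the call threshold, Poisson(3) shared loops
per bait, odds ratio 4 for the loop coupling, twin probability 0.1 and 12
planted targets.

Planted structure, in generation order:

- **Layout.** Enhancers sit on a lattice with inter-enhancer gaps above
  the 12.5 kb stitching distance, so stitching can never fuse two planted
  elements and a 10 kb bin never touches two enhancers; genes occupy the
  gaps with clearance beyond the 2.5 kb TSS-exclusion half-width. Domains
  are laid out independently with guard gaps above the 25 kb merge
  distance. Domain densities are drawn so the three classes are separated
  (super 12-20, standard 2.1-5, low 1.2-2.2 signal units; the standard
  band times its lengths stays above 3,780, the low band below), making
  the class labels recoverable exactly — the truth file is a contract,
  not an approximation.
- **DE <-> domain coupling.** Up/down status is sampled with weights 6 /
  2 / 1 for genes in super / standard / no domain. Planted targets are
  chosen first among super-domain genes with distinct bait bins and
  forced up.
- **Enhancer <-> domain coupling.** Gain probability 0.40 / 0.15 / 0.05
  and loss probability 0.25 / 0.10 / 0.05 by domain class. Gains and
  losses are planted at |log2FC| >= 1.2 and statics at <= 0.1, leaving a
  margin around the 0.75 threshold that absorbs the small shift
  introduced by cross-sample normalization, so planted status is always
  recovered.
- **Loop couplings.** Shared loops are Poisson per bait with distal ends
  mostly at enhancer bins (20% background). Condition-unique loops are
  planted per *enhancer*: each enhancer receives at least one unique dKO
  loop with baseline probability 0.25, scaled to odds ratio
  `loop_coupling_or` for gain enhancers (unique WT loops symmetrically
  for losses). Receiver planting makes the enhancer-level contingency
  table a consistent estimator of the planted odds ratio; weighting
  individual loop draws instead would saturate and inflate the
  enhancer-level association well beyond the nominal value. Baits of
  upregulated genes are favoured (weight 2.5) when unique dKO loops are
  placed, planting the expression/net-loop-gain coupling. A fraction 0.1
  of unique loops is emitted together with a +-1-bin shifted twin in the
  other condition; because each twin event marks one loop on each side,
  the measured adjacent-shift fraction is about `2*rho/(1 + rho)`, not
  `rho` itself.
- **Target exactness.** Gain enhancers never receive loops — in either
  condition, at any stage — from baits of upregulated non-target genes,
  and every planted target is guaranteed one retained dKO loop onto a
  gain enhancer plus a strict net loop gain. The planted targets are
  therefore exactly the genes satisfying the target criteria.
- **Decoys.** About 10% extra sub-threshold loops (score < 5) are written
  to the raw loop files to exercise the score filter, and 5% of genes are
  shorter than 1 kb to exercise the matched-sampler length filter.

`generate_null_dataset()` removes every coupling (uniform gain/loss
probabilities 0.2, odds ratio 1, uniform DE placement, no boost, no
planted targets, no exclusivity constraints) for type-I calibration.

**What the generator does not emulate:** read-level noise, irregular
coverage, peak-caller boundary error, overlapping or nested regulatory
elements, trans-chromosomal contacts, and realistic score distributions.
Passing tests demonstrate the pipeline's logic and statistical
calibration under the planted model, not performance on real sequencing
data.

## Simulation sizes and calibration checks

The repeated-simulation checks run at a reduced configuration
(`synth_config_small()`: 500 genes, 800 enhancers on a 14 Mb chromosome,
12 / 80 / 30 domains — the default densities preserved): 1,000 null
datasets for type-I calibration of the super-stratum test (rejection at
about the nominal 5%), 200 coupled datasets for power (Holm-adjusted
p < 0.01 with positive residuals in the planted cells), and 100
bootstrap replicates for confidence-band coverage. The end-to-end target
recovery check runs at the full default size. Rejection is measured on
the super stratum, the stratum carrying the strongest planted coupling.

## Known limitations

- Loop identity is exact bin equality; loops spanning bin boundaries on
  real data would need the upstream binning to be consistent between
  conditions.
- Only distal-end shifts are considered by the adjacent-shift analysis;
  bait-side shifts are not matched.
- The chi-square tests assume counts large enough for the asymptotic
  distribution; very sparse strata are skipped rather than tested
  exactly.
- Multi-chromosome input is supported throughout the interval algebra,
  but the synthetic generator emits a single chromosome by default.
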