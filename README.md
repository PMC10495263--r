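# macroloop

Integrative analysis linking broad histone-variant chromatin domains,
differential enhancer activity and promoter-anchored chromatin loops to
gene-expression changes.

## The problem

MacroH2A is a histone H2A variant associated with condensed chromatin. In
fibroblasts lacking both macroH2A genes (a WT vs dKO comparison),
inflammatory genes become hyperinducible, and the mechanism runs through
chromatin architecture: broad macroH2A chromatin domains (MCDs) harbour
the genes and enhancers that change, enhancers inside the most highly
macroH2A-enriched ("super") domains preferentially gain H3K27ac, and
promoter-capture chromatin loops rewire toward those hyperacetylated
enhancers. `macroloop` reimplements that analysis chain as a reusable,
tested R package for anyone who has:

- domain-level occupancy peak calls plus a coverage track (CUT&RUN-style),
- per-condition H3K27ac peaks and per-sample coverage tracks (ChIP-seq),
- a differential-expression gene table (TSV with TPM, log2FC, adjusted p),
- per-condition promoter-anchored loop calls at fixed bin size
  (CHiCAGO-style scores).

## The methods at its core

- **ROSE-style ranked-curve classification**: elements are ranked by
  signal (size-normalized for domains, raw for enhancers), both axes
  scaled to [0, 1], and the class cutoff placed where the curve's slope
  reaches 1 — super-MCDs and super-enhancers are the elements above the
  elbow. Non-super domains split at density x length = 3,780 into
  standard and (excluded) low domains.
- **Cross-sample enhancer normalization**: each sample's signal is divided
  by its mean over all elements; gains and losses are called at
  |log2FC| >= 0.75 on condition means.
- **Loop comparison at fixed 10-kb bins**: retained at score >= 5; shared
  iff the identical (bait, distal) bin pair exists in both conditions;
  one-bin distal shifts quantified by greedy matching; per-gene loop
  counts summed over all baits of a gene.
- **Stratified chi-square tests** of enhancer-status x loop-relation and
  DE-status x net-loop-change, per MCD stratum, with Pearson residuals
  `(O - E)/sqrt(E)` and Holm adjustment across strata.
- **Expression-matched control sampling**: static genes within 25% of a DE
  gene's WT TPM, >= 1 kb, seeded and duplicate-free.
- **Bootstrap signal profiles**: metagene and point-centered means with
  percentile-bootstrap 95% bands.
- **Target intersection**: upregulated genes looped (either condition) to
  an enhancer gaining H3K27ac, flagged for net loop gain and pathway
  membership.

A seeded synthetic-data generator (`generate_dataset()`) emits all four
input layers with planted couplings and a ground-truth record, so the
entire pipeline is exercisable and testable without any downloads. See the
methods vignette (`vignettes/macroloop-methods.Rmd`) for the model,
parameter choices and limitations.

## Worked example

```r
library(macroloop)

b   <- generate_dataset(synth_config_small(seed = 42))  # 500 genes, 800 enhancers
res <- analyze_bundle(b, list(run_profiles = FALSE))

unlist(res$summary$domains$by_class)
#>      low standard    super
#>       30       80       12

unlist(res$summary$enhancers$by_status)
#>   gain   loss static
#>    149     93    558

res$assoc_enh$summary[, c("stratum", "chi2", "dof", "p_adj")]
#>           stratum      chi2 dof        p_adj
#> super       super 32.802765   4 3.932558e-06
#> standard standard  5.779401   4 2.162396e-01
#> none         none 22.238301   4 3.593490e-04

head(res$targets[, c("gene_id", "count_wt", "count_dko", "net_change")], 3)
#>    gene_id count_wt count_dko net_change
#> 1:   G0165        6         7          1
#> 2:   G0166        4         5          1
#> 3:   G0215        6         7          1
```

The domain counts recover the planted 12 super / 80 standard / 30 low
domains exactly. The enhancer-status x loop-relation association is
strongest in the super-MCD stratum (chi-square 32.8, Holm-adjusted
p = 3.9e-06), reflecting the planted odds-ratio-4 coupling between
H3K27ac gain and dKO-unique looping; and the reported target genes are
the planted ones, each with a net gain of loops in the knockout. File
inputs work the same way through `run_pipeline()` with a YAML or list
configuration naming the input paths (see `?run_pipeline`); it writes a
report directory with every intermediate table and a deterministic
`summary.json`.

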