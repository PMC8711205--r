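# chromintegrate

Integrative analysis of chromatin accessibility, H3K56ac occupancy and
linker histone H1 stoichiometry for studies of histone deacetylase
inhibitor (HDACi, e.g. valproic acid) induced differentiation of mouse
embryonic stem cells.

HDAC inhibition remodels chromatin on several levels at once: locus-specific
accessibility (measured by ATAC-seq), occupancy of the core-domain
acetylation mark H3K56ac (measured by CUT&RUN), and the global stoichiometry
of linker histone H1 (measured by reverse-phase HPLC of extracted histones).
This package implements the computational layer that connects those assays:

* **SEACR-style peak calling and post-processing for CUT&RUN.** A bedGraph
  track is segmented into *signal blocks* — maximal runs of strictly
  positive coverage — each scored by its total signal
  (AUC = Σ value × segment length). The stringent caller keeps the top
  ⌈θ·N⌉ blocks by AUC (default θ = 0.05), a half-mean filter then removes
  peaks with AUC below half the file mean, replicate consensus keeps union
  spans of peak pairs sharing ≥ 300 bp, and condition-unique peaks are
  consensus peaks with zero overlap against the other condition.
* **Differential chromatin accessibility.** For each ATAC region with
  pooled treated count *k* out of *n* total, an exact two-sided binomial
  test against π = (treated library size)/(total library size), with the
  minimum-likelihood two-sided convention; fold change is the ratio of
  pseudocounted mean CPMs (c = 0.5). Regions are *gained-open* when
  p < 0.001 and FC > 4, *gained-closed* when p < 0.001 and FC < 1/4,
  otherwise *unchanged*; analysis is restricted to TSS windows (5,000 bp
  upstream to 3,000 bp downstream, strand-aware).
* **Annotation.** Peaks map to genes within a 10,000 bp genebody flank
  (largest overlap wins; promoter takes precedence over genebody), and
  differential peaks are summarised by the percentage overlapping each
  transposable-element class (LTR/SINE/LINE/DNA).
* **Integration at TSSs.** Each gene is classified by its joint ATAC ×
  H3K56ac evidence: **I** gain accessibility & gain H3K56ac, **II** lose
  both, **III** lose accessibility while gaining H3K56ac, **IV** the
  remaining quadrant, or *uncalled*.
* **H1 stoichiometry.** A214 chromatogram peaks are integrated
  (trapezoid over a labelled retention window, linear endpoint baseline),
  adjusted per peptide bond (A214 scales with bond count), and expressed
  per nucleosome by dividing by half the H2B area (two H2B copies per
  nucleosome):
  `ratio_s = area_s / (area_H2B / 2)`, `total = Σ_s ratio_s`.

Seeded synthetic-data generators emit every input with a truth manifest, so
the whole chain is testable end to end without sequencing data.

## Worked example

Simulate a study-sized bundle (2 × 2 Mb genome, 200 genes, 2 conditions ×
2 CUT&RUN replicates, ~2,100 ATAC regions, control/treated chromatograms)
and run the full pipeline:

```r
library(chromintegrate)
cfg <- sim_config(seed = 3)          # plants I=11, II=73, III=5 categories
b   <- simulate_bundle(cfg, "bundle")
res <- run_pipeline(bundle_config(b$paths, "out"))

table(res$differential$direction)
#> gained-closed   gained-open     unchanged
#>           128            61          1900

res$category_counts
#>        I       II      III       IV uncalled
#>       11       72        5        0      112

res$h1_comparison
#> $exact     16.89609
#> $truncated 16
```

The 128/61 differential regions are the 123 planted 8-fold effects plus a
handful of borderline calls; the integration recovers the planted
categories (II shows 72 of 73 here because one planted control block was
split by a zero-coverage bin in one replicate and missed the 300 bp
consensus floor — the track-level chain is bounded by the sensitivity/FDR
checks, not exactness). The H1 stage reports total H1/nucleosome ratios of
0.575 (control) and 0.672 (treated), a 16% rise; the generating truth is
0.58 and 0.67. From the two *published* ratios the package computes:

```r
percent_change(0.58, 0.67)
#> $exact     15.51724
#> $truncated 15
```

A thin CLI wraps the same functions
(`inst/cli/chromintegrate.R simulate | callpeaks | atac-diff | annotate |
integrate | h1quant | run-all`).

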