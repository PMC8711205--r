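---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chromintegrate implements the analysis layer of an HDAC-inhibitor
differentiation study in mouse embryonic stem cells: sparse-enrichment
peak calling for CUT&RUN, threshold-based differential chromatin
accessibility for ATAC-seq, gene/TE annotation, joint classification of
accessibility and H3K56ac changes at transcription start sites, and
RP-HPLC quantification of linker histone H1 stoichiometry. This vignette
records the models, the parameters that matter, and the decisions taken
where the procedure was genuinely open.

## Coordinates and interval conventions

All genomic coordinates are 0-based half-open (BED convention), the native
convention of bedGraph and BED inputs; 1-based inputs (e.g. GTF-derived
gene tables) must be converted at the reader boundary. The TSS of a
plus-strand gene is its body start. For a minus-strand gene we take the
**last base of the body** (`end - 1`): nearest-base conventions differ by
±1 between tools and no convention is universal, so the choice is fixed
here and applied consistently. The strand-aware TSS window with extents
`up`/`down` is `[tss - up, tss + down)` on plus and
`[tss - down + 1, tss + up + 1)` on minus strands, giving length
`up + down` on both strands; windows are clipped at the chromosome origin.

"Overlap of at least 300 bp" between replicate peaks is interpreted as
**shared length ≥ 300 bp**, not as a centre-to-centre or gap distance; a
distance-based reading (gap ≤ 300 bp) would admit non-overlapping peaks
and does not compose with the zero-overlap uniqueness rule used across
conditions.

## CUT&RUN peak calling

A bedGraph track is segmented into *signal blocks*: maximal runs of
strictly positive coverage, where abutting positive records merge and any
zero-valued or absent stretch separates blocks. Each block is scored by
its total signal, AUC = Σ value × segment length (signal·bp), and its
maximum value. The stringent caller retains the top ⌈θ·N⌉ blocks by AUC
with θ = 0.05 by default; ties are broken by coordinate so the call is
deterministic. Only the numeric-threshold mode is implemented — the study
configuration — not the IgG/control-track mode or relaxed thresholding.

Post-processing decisions:

* **Half-mean filter.** "Signal value" is read as the block's total
  signal (AUC), the primary score by which sparse-enrichment callers rank
  and report regions; the maximum value is an alternative reading that we
  expose in the output but do not filter on. The mean is computed once
  over the input set (a single normalisation pass, not iterated to a
  fixed point), so the filter can legitimately remove more than half of a
  heavy-tailed file. The maximum-AUC peak can never be removed.
* **Replicate consensus.** Every cross-replicate peak pair sharing
  ≥ `min_overlap` bp (default 300) contributes the union span of the
  pair; chained overlapping pairs merge into one region whose AUC is the
  sum of the distinct contributing peaks. Union rather than intersection
  is used because downstream gene mapping tolerates broad enrichment
  domains; intersection would fragment them.
* **Condition-unique peaks.** Uniqueness is the strictest reading: zero
  shared bases against every peak of the other condition's consensus set.
  A single-base overlap disqualifies.

## Differential accessibility

The published analysis used a count-model fit (DESeq2) whose internals
are out of scope here; the decision layer — p < 0.001 **and** linear fold
change > 4 (or < 1/4), restricted to TSS windows — is the contribution
this package reproduces. In its place we use a defined, deterministic and
oracle-checkable test: for each region, pooled treated counts *k* out of
pooled total *n* are tested against the library-size split
π = Σ treated library sizes / Σ all library sizes with an exact two-sided
binomial test, using the minimum-likelihood convention (the sum of
probabilities of all outcomes no more likely than the observed one; this
is also R's `binom.test` convention — doubling the one-sided tail is the
noted alternative). Fold change is `(mean treated CPM + c)/(mean control
CPM + c)` with pseudocount c = 0.5 CPM to keep empty regions finite; the
threshold applies to this pseudocounted, unshrunken ratio. Regions with
n = 0 are flagged untested (p = 1, log2FC = 0). No multiple-testing
correction enters the decision rule — the published rule is a raw p-value
cutoff — but a Benjamini–Hochberg FDR column is emitted for reference.

The pooled binomial test conditions away library-size differences but
assumes counts are close to Poisson across replicates. It is therefore
calibrated for technical/counting noise, and anticonservative under
strong biological overdispersion, where a dispersion-modelling method is
required. The synthetic generator's default dispersion (below) reflects
the regime in which this test is valid; this is a stated limitation, not
a claim about biological replicates in general.

## Annotation

Peaks are assigned to the gene whose 10,000 bp-flanked body they overlap
most (ties to the smallest gene start — the published description says
"nearest gene" without a tie rule). A peak overlapping the assigned
gene's TSS window is a *promoter* peak — promoter takes precedence over
genebody — otherwise *genebody*; peaks hitting no flanked gene are
*intergenic*. The promoter definition reuses the ATAC TSS window
(−5000/+3000); the source analysis does not state its promoter window, so
this is a documented assumption.

TE overlap proportions: for each direction (gained-open/gained-closed)
and TE class, the percentage of direction-*d* peaks overlapping ≥ 1 TE of
that class. A peak overlapping two classes counts once in each, so
percentages may sum above 100 within a direction. The denominator is the
number of direction-*d* TE-overlapped peaks (the quantity the published
figure plots); a switch selects the all-differential-peaks denominator
(the methods-text reading). Zero denominators yield no row rather than
NaN.

## Integration at TSSs

H3K56ac gain/loss at a gene is presence-based — a treated-unique (gain)
or control-unique (loss) consensus peak overlapping the gene's TSS window
— not a quantitative signal comparison, matching the presence-based
definition of condition-unique peaks. The same −5000/+3000 window is used
as for the ATAC restriction; co-occurrence in the window is required, not
mutual overlap of the ATAC and CUT&RUN peaks themselves. The gene's ATAC
direction comes from its strongest |log2FC| TSS-restricted region.
Categories I–III follow the published enumeration; the fourth quadrant
(gain accessibility, lose H3K56ac) logically exists and is emitted as
category IV rather than silently dropped, so reporting is lossless. Genes
with both gain and loss H3K56ac evidence are flagged ambiguous and left
uncalled; genes missing either line of evidence are uncalled.

## H1 stoichiometry from chromatograms

Peak areas are trapezoidal integrals of the A214 trace over labelled
retention-time windows after subtracting a linear baseline through the
signal values at the window edges (the integration method is not
specified in the source; endpoint-linear baseline plus trapezoid is the
standard chromatography default, and a no-baseline option is provided).
Negative baseline-subtracted areas clip to zero with a warning. Since
A214 absorbency scales with peptide-bond count, areas are divided by each
protein's bond count (residues − 1) so adjusted areas are proportional to
molar amounts; a bond-count *ratio* to a reference protein would differ
only by a global constant that cancels in every ratio. Subtype bond
counts are configuration inputs (a TSV), not hard-coded. The
per-nucleosome ratio divides each adjusted H1 area by **half** the
adjusted H2B area — two H2B copies per nucleosome — and the total ratio
is the sum over subtypes (additive by construction). Percent changes are
reported exactly and truncated toward zero to an integer, the convention
in which such figures are quoted.

## The synthetic data generator

Generators are pure functions of `sim_config()`: every stream derives
from the master seed by a fixed offset, so outputs are byte-identical
under a fixed seed and adding a generator never perturbs existing ones.
Defaults encode the study conditions at desk scale:

* **Genome**: 2 chromosomes × 2 Mb, 200 genes placed one per 20 kb slot
  (bodies 2–8 kb, random strand) so bodies and TSS windows never overlap;
  300 TEs of classes LTR/SINE/LINE/DNA placed uniformly, overlapping
  freely as real repeats do.
* **CUT&RUN tracks**: Poisson background, 1 count per 10 bp bin, with
  planted 500 bp blocks at 8× background centred on designated gene TSSs:
  60 condition-shared blocks, gain blocks (categories I and III) in
  treated only, loss blocks (category II) in control only; replicates
  share locations with independent noise. On a zero background the fold
  acts as the absolute enriched rate.
* **ATAC counts**: 2,000 random regions (200–1000 bp) plus one 500 bp
  region per category gene TSS; negative-binomial counts with mean 50 per
  region per sample and dispersion 0.001 (variance/mean ≈ 1.05 at this
  depth, i.e. counting noise with mild technical excess — the regime in
  which the exact pooled test is calibrated); planted regions multiply or
  divide the treated mean by 8; library sizes are column sums.
* **Planted categories**: I = 11, II = 73, III = 5 by default, matching
  the scale of the gene sets the integrated analysis is meant to surface.
* **Chromatograms**: Gaussian peaks (σ = 0.25 min) with analytic area
  amount × bonds, on a linear baseline (2 mAU offset, 0.1 mAU/min drift)
  with 0.2 mAU Gaussian detector noise — typical UV-detector magnitudes.
  The `control` and `treated` amount profiles are constructed so the true
  total H1/nucleosome ratios are 0.58 and 0.67 with subtype shifts in the
  published directions (H1a/H1b/H1e/H1.0 up, H1d down, H1c flat, H1.0
  nearly absent in control); a `balanced` profile gives every subtype a
  well-sized peak for per-subtype recovery checks, since relative error
  on a near-zero peak is dominated by baseline noise and is not a
  meaningful recovery metric.

What the generator does **not** emulate: read-level artefacts (duplicates,
mappability, GC bias), fragment-size structure, biological replicate
overdispersion, correlated background (chromatin domains), co-eluting
chromatogram peaks (the H1d/H1e fraction is separable by construction;
resolving co-elution is a mass-spectrometry problem, out of scope).
Passing tests therefore demonstrate algorithmic correctness and
calibration under the stated noise models, not robustness to every
artefact of real data.

## Validation strategy and problem sizes

The test suite checks every interval operation against per-base and
all-pairs brute-force oracles (50+ seeded instances, up to 5,000
intervals), the exact test against full enumeration of the binomial
distribution, and chromatogram integration against closed-form Gaussian
areas. End-to-end checks run at the default study scale: 20 seeded
simulations for planted-block recovery (sensitivity ≥ 0.9, FDR ≤ 0.1
through the full calling chain), null calibration (fraction of null
regions with p < 0.001 at most 0.002) and planted-effect power
(≥ 90% recovered with correct direction), and byte-identical pipeline
reruns under a fixed seed. Integration category counts are asserted
exactly for manifest-planted (unambiguous) evidence peaks: on noisy
tracks a planted block is occasionally split by a zero-coverage bin such
that neither fragment clears the 300 bp consensus floor, which is a
property of the replicate-consensus rule, bounded by the sensitivity
check, not an integration error.

## Known limitations

* The exact pooled test replaces a dispersion-modelling fit; see above.
* Consensus is defined for two replicates (the study design); more
  replicates fold left: `((r1 ∘ r2) ∘ r3)`.
* `call_peaks` keeps a fixed fraction of blocks, so with few blocks the
  ceiling makes the call conservative (a single block is always kept).
* Chromatogram windows must be non-overlapping; co-eluting species are
  quantified as one peak.
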