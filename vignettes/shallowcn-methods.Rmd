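---
title: "Copy number from shallow WGS: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number from shallow WGS: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`shallowcn` turns binned read counts from low-coverage whole-genome
sequencing (~0.1–3× depth, as obtained from low-input or FFPE-derived DNA)
into three-state copy-number profiles, and provides the quality and
comparison machinery around them. This vignette documents the underlying
models, every tunable that matters, the numerical choices, and what the
synthetic validation does and does not demonstrate.

## The read-depth model

The unit of analysis is a fixed bin grid: 0-based half-open windows
(default 50 kb) tiling each chromosome, each annotated with its GC
fraction. For a bin with copy number $c$ in a sample of tumor purity
$\rho$ on a diploid background, the expected depth ratio is

$$ r(c, \rho) = \frac{\rho\,c + (1-\rho)\,2}{2}, \qquad
   \text{expected log2 ratio} = \log_2 r . $$

So copy number 2 maps to log2 ratio 0, CN 3 at purity 1 to
$\log_2 1.5 \approx 0.585$, CN 4 at purity 0.5 to $\log_2 1.5$ as well —
purity compresses all events toward 0.

### GC normalization

Observed depth is confounded by a unimodal response to bin GC content.
`gc_normalize()` estimates expected count as a function of GC **without a
matched normal** and centers ratios so the copy-number-neutral baseline
maps to 0:

1. A robust anchor curve — a quadratic fit through per-GC-decile count
   *medians*, weighted by stratum size — gives preliminary ratios. Medians
   make the anchor insensitive to altered regions, and the quadratic form
   extrapolates sensibly at the GC extremes where strata are thin (a flat
   or piecewise-linear tail misstates expected depth exactly where the
   bias is largest).
2. Bins whose preliminary log2 ratio lies within `baseline_window`
   (default 0.25 log2 units) of the running median form the *baseline
   cluster*. The requested model — degree-2 polynomial (`fit = "poly"`,
   default) or interpolated GC-decile running medians (`"runmed"`) — is
   then fit on baseline bins only, unweighted and untrimmed, and the
   selection is refined for `baseline_iterations` (default 3) passes.
3. Final ratios are divided by the baseline median before the log2, so
   the neutral cluster centers at 0.

Fitting and centering on the baseline cluster rather than on all bins
matters once a substantial fraction of the genome is altered: a fit over
all bins absorbs part of the CNA signal (compressing event amplitudes) and
the global median drifts off the diploid level. On majority-diploid data
the baseline median and the genome-wide median coincide, so the
conventional "median maps to CN 2" contract is preserved (the package
asserts $|\mathrm{median}| < 0.02$ there). The 0.25 window cleanly
excludes events with $|\log_2| \ge 0.4$; at low purity, events can fall
inside the window and are then treated as baseline — the standard
limitation of baseline-free normalization.

Zero-count bins are masked with reason `zero-count` rather than
log-transformed with a pseudocount: at WGA-like 0.2× coverage a pseudocount
would fabricate deep-loss signal in what is actually missing data.

### Blacklist masking

Published problematic regions (centromeric and other repetitive sequence)
are masked before segmentation: any bin overlapping a blacklist interval by
at least 1 bp is flagged, its value retained for audit but excluded from
all computation. Masked fraction is tracked per reason (`blacklist`,
`zero-count`, `user`).

## Segmentation: circular binary segmentation

`segment_cbs()` implements standard CBS. For the non-missing markers
$x_1,\dots,x_m$ of a chromosome, every arc $(i, j]$ of the circularised
sequence is scored with the pooled-variance two-sample $t$ statistic
between arc and complement; the maximizing arc is accepted as a split when
its permutation p-value (marker-label shuffles) is below `alpha`, and the
parts are segmented recursively. Defaults: `alpha = 0.01`,
`n_permutations = 1000`, `min_bins_per_segment = 3`, pruning tolerance
`prune_tol = 0.05` log2 units — conventional CBS settings, all exposed.

Numerical and algorithmic choices:

* The $O(m^2)$ scan and the permutation loop are compiled (Rcpp); the
  permutation RNG is R's own stream, so results are reproducible under
  `set.seed()` / the `seed` argument.
* **Early stopping**: permutations halt as soon as the exceedance count
  already forces $p \ge \alpha$ regardless of the remaining draws
  (rejection), or once $\hat p < \alpha/2$ after at least 300 draws
  (acceptance). This changes borderline decisions only within the
  permutation-noise band and cuts runtime roughly tenfold on null
  segments.
* A pooled variance of exactly zero (noiseless constant data) is floored
  at $10^{-24}$; the max statistic is then 0 and no split is accepted, so
  noiseless constant chromosomes always return one segment.
* **Pruning** merges adjacent segments whose means differ by less than
  `prune_tol`, smallest difference first, recomputing means as segments
  coalesce.
* **Masked gaps**: a run of more than `max_gap` (default 10) consecutive
  masked bins splits the chromosome; segments never bridge such gaps.
  This prevents centromere-spanning segments. Smaller gaps are bridged.
* Segment extents run from the first member bin's start to the last
  member bin's end; `n_bins` counts non-missing markers only.

Calls are made per segment with strict inequalities: gain iff mean log2
ratio $> 0.15$, loss iff $< -0.15$, neutral otherwise — boundary values are
neutral. The ±0.15 default corresponds to the conventional shallow-WGS
threshold for detecting single-copy events diluted by purity and noise.

Sex chromosomes receive no special handling: the pipeline is
genome-agnostic and processes whatever chromosomes the grid names.

## MAPD

The noise metric is the median absolute pairwise difference
$\mathrm{MAPD} = \mathrm{median}\,|x_{i+1} - x_i|$ over markers ordered by
genomic position, computed on **bin-level normalized values** (not segment
means). Because successive differences cancel slowly-varying structure,
MAPD reflects measurement noise rather than biology: for i.i.d. marker
noise of scale $\sigma$ it rises monotonically with $\sigma$
($\approx 0.954\,\sigma$ for Gaussian noise), while a noiseless
piecewise-constant profile of any complexity scores 0.

Two decisions the definition leaves open:

* Pairs spanning a chromosome boundary are excluded — a cross-chromosome
  difference is not a biological adjacency.
* Missing markers are *skipped* by default (differences taken between
  consecutive non-missing markers within a chromosome), which keeps the
  marker count comparable between samples with different masking;
  `pairing = "strict"` instead drops any pair with a missing member.
* MAPD is pooled genome-wide (not per chromosome then pooled); with
  boundary pairs excluded the two differ only in weighting.

## Profile comparison

`profile_to_states()` quantizes a segmented profile back onto the grid by
the bin-midpoint rule; bins outside all segments are `masked`. Comparison
is therefore at the pipeline's native bin resolution; segment-level inputs
from external callers can be imported via `read_seg()` and quantized the
same way.

`concordance()` classifies every base pair compared (bins unmasked in
*both* samples — masked regions cannot be fairly compared, so they are
excluded from the denominator) into exactly one of: shared gain, shared
loss, shared neutral, CNA private to either sample (other sample neutral),
or *conflict* (opposite CNA types at the same locus). The explicit
conflict class keeps the accounting identity exact:

$$ \text{shared CNA} + \text{a-only} + \text{b-only} + \text{conflict} +
   \text{shared neutral} = \text{total compared}. $$

`shared_fraction` is the fraction of compared bp concordant across all
three states; `shared_cnv_fraction` restricts the view to bp where at
least one sample carries a CNA. `shared_neutral_bp()` exposes the
complementary subtraction account (total − shared CNA − sample-only CNA).

`shared_regions()` decomposes the genome, per event type independently,
into maximal intervals labeled by the exact subset of samples carrying
that event — intervals carried by ≥ 2 samples are `shared`, by exactly one
`sample_only`. Gain and loss never match each other.

`cna_bin_correlation()` mirrors the standard replicate-consistency check:
normalized bin values are extracted from the union of CNA calls across the
supplied profiles (optionally minus filter regions), samples are
correlated pairwise (Pearson, pairwise-complete), and the correlation
matrix rows are clustered by Euclidean distance with complete linkage (the
`hclust` default in this analysis tradition; exposed via `linkage`).

## The synthetic-data generator

`simulate_counts()` draws bin counts from a negative binomial with mean

$$ \mu_b = \underbrace{\frac{\text{coverage} \times \text{bin size}}
   {\text{read length}}}_{\text{calibration}} \; r(c_b, \rho)\;
   g(gc_b), $$

where $g$ is a quadratic response peaked at GC 0.5 with amplitude
`gc_bias_strength`, normalized to mean 1 over the grid, and the
negative-binomial `dispersion` is the size parameter (large = Poisson).
Defaults were fixed once as the study conditions the package validates
under:

| parameter | default | rationale |
|---|---|---|
| `bin_size` | 50 kb | the standard shallow-WGS window |
| `read_length` | 75 bp | paired-end 75 chemistry; makes coverage↔count calibration interpretable |
| `mean_coverage` | 1.3× | reference depth of a standard-input library |
| `dispersion` | 50 | bin-level log2 noise sd ≈ 0.2 (MAPD ≈ 0.2), typical of usable FFPE libraries |
| `gc_bias_strength` | 0.3 | moderate unimodal bias; strength 0.5 halves depth at GC 0.3/0.7 |
| `dropout_fraction` | 0 | dropout is an amplification artifact, applied via `degrade_wga()` |
| purity | 1 | tumor cellularity of the motivating material is unknown; purity stays a free parameter |

`degrade_wga()` models amplification damage as mean-preserving variance
inflation (bin count $n$ resampled as NB with mean $n$ and variance
$f\,n$, default $f = 4$, standing in for duplicate-read inflation) plus
coverage dropout (default 0.85, i.e. <15% of bins covered).
`downsample_counts()` replaces each count by a Binomial(count, fraction)
draw — the count-level equivalent of read-level down-sampling, and
distributionally composable: thinning by $a$ then $b$ equals thinning by
$ab$.

Counts are simulated at bin level, not read level: the analysis consumes
binned coverage, and read-level simulation would add cost without
exercising additional code. A minimal SAM fixture writer exists solely to
test the alignment-file adapter (`count_reads_in_bins()`), which assigns
each mapped, filter-passing read to one bin by its leftmost position.

**What the generator does not emulate**: FFPE damage chemistry
(deamination, fragment-length effects), library-preparation base
composition artifacts, mappability variation, allelic signal, and
subclonal heterogeneity. Passing recovery tests therefore demonstrates the
*algorithmic* correctness of normalization, segmentation, calling and
accounting under realistic count noise — not robustness to every artifact
of real FFPE libraries.

## Randomness and reproducibility

Every stochastic operation takes an explicit integer seed and expands it
into a private substream (`withr::with_seed` internally), so stages are
individually reproducible and do not perturb the caller's RNG or each
other. File outputs carry a provenance header (package version, config
hash, seed; timestamps only on request), so reruns are byte-identical.

## Validation problem sizes

The shipped validation experiments (test suite and
`scripts/acceptance.R`) use genomes of 2–4 chromosomes × 20 Mb at 50 kb
bins (800–1600 bins), truths of 5–8 events of 50–70 bins with
$|\log_2| \ge 0.4$, and 5–20 replicate seeds per experiment — sizes chosen
so the full suite completes in minutes on one CPU while each experiment
retains enough bins and replicates for its pass threshold to be stable.
The titration experiment profiles the same simulated sample at 2.2×, 1.3×
and 0.6×; the WGA contrast compares each unamplified sample with its own
degraded copy, paired by seed.

## Known limitations

* No allele-specific analysis or LOH: shallow coverage cannot support
  genotyping, so balanced events are invisible.
* Fixed diploid baseline; no purity/ploidy estimation. In near-triploid
  genomes the baseline cluster is mis-centered by construction.
* No mappability weighting: the blacklist is the only mechanism for
  removing alignability artifacts.
* Events shorter than one bin (50 kb by default) are below the design
  resolution.
* The permutation test is approximate under early stopping; with
  `alpha = 0.01` the affected decisions are those with
  $p \approx \alpha$, where either outcome is defensible.
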