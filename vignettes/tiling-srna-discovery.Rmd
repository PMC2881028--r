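---
title: "Discovering bacterial small RNAs from tiling arrays with srnatile"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering bacterial small RNAs from tiling arrays with srnatile}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnatile)
```

## The problem

Bacterial genomes carry many small non-coding RNAs (ncRNAs) — regulatory
sRNAs, riboswitches and other cis-regulatory elements — most of which sit in
the intergenic regions (IGRs) between annotated genes and are invisible to
protein-centric annotation. A genome tiling array (overlapping oligo probes
at a regular spacing across the whole genome) measures transcription without
committing to an annotation, so it can confirm which computationally
predicted ncRNAs are actually expressed, and under which growth conditions.

`srnatile` implements that analysis end to end for a multi-replicon
bacterial genome (a chromosome plus plasmids, circular by default):

1. extract IGRs from a genome annotation;
2. map a compilation of predicted ncRNA sequences onto the IGRs by local
   alignment with E-value statistics, merging overlapping hits into
   non-redundant *candidate regions*;
3. normalize raw probe intensities against an artificial reference array;
4. summarize the probes of each candidate region into one value per
   condition by median polish;
5. call regions *expressed* per condition with a robust noise threshold,
   and *differentially expressed* from the spread of their profiles;
6. profile the results: hierarchical clustering of expression profiles,
   per-replicon density and hotspot scanning, and a cross-species
   conservation matrix.

A synthetic-data generator reproduces the whole study design with known
ground truth, so every stage is testable without any external download.

## Sequence matching and E-values

Predictions are matched to IGRs with a local aligner (match +1, mismatch
−2, gap of length $g$ costing $5 + 2g$ — a classic nucleotide scheme,
configurable via `scoring_scheme()`). Both query orientations are searched.
Significance uses Karlin–Altschul statistics,

$$E = K\,m\,n\,e^{-\lambda S},$$

with $\lambda$ the positive root of
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ for the background base
frequencies (computed by `karlin_lambda()`; for +1/−2 on a uniform
background $\lambda = \ln\frac{3+\sqrt{21}}{2} \approx 1.333$) and
$K = 0.46$ by default. Raw sequence lengths are used with no edge-effect
correction — a deliberate simplification relative to BLAST's length
adjustment, conservative for the short sequences involved.

The aligner is exact where exactness is affordable and seeded where it is
not: when the dynamic-programming table fits under `exact_limit` cells
(default $4\times10^6$) the full affine-gap local recursion is run, so the
reported top score *is* the Smith–Waterman optimum; for genome-scale
subjects an 11-mer index drives seed-and-extend, where every extension is
itself an exact windowed dynamic program. Reported scores are therefore
always true local-alignment scores of the reported intervals; the seeded
path can only miss loci that share no 11-mer word with the query, which at
the ≥90% identity typical of prediction-to-genome matches is negligible.
`N` never matches anything, including itself.

Hits at or below the E-value threshold ($10^{-5}$ by default) are projected
onto genomic coordinates (wrapped IGRs split at the origin) and merged
transitively wherever their genomic intervals overlap by at least 1 bp on
the same replicon, strand ignored — an unstranded tiling signal cannot
distinguish strands, so neither does the merge. The result is a set of
pairwise non-overlapping candidate regions, each recording its supporting
predictions and the number of distinct source studies.

## Normalization and summarization

All preprocessing happens on the log2 scale (the microarray convention) on
non-background-corrected intensities; there is deliberately no background
subtraction stage. The *artificial reference array* is the per-probe median
across all arrays. For each array $j$ the log-ratio $M = x_j -
\mathrm{ref}$ is smoothed against the anchor $A = \mathrm{ref}$ — the
reference value itself, **not** the usual $(x_j + \mathrm{ref})/2$ — with a
degree-1 local regression using tricube weights over the `span` fraction
(default 25%) of nearest probes, and the fitted curve is subtracted. Using
the reference as the anchor means the reference is a fixed point of the
procedure: normalizing the reference against itself changes nothing, and a
constant per-array offset is removed exactly. Robustness re-weighting
iterations default to 0 and are configurable. One caveat worth stating:
like any non-projection smoother, local regression is only approximately
idempotent — a second pass moves already-normalized data by a small
fraction of the first pass (it is exactly idempotent when the log-ratio is
linear in $A$).

Each candidate region is assigned the probes that overlap it by at least
half the probe length (majority overlap keeps flanking-gene signal out of
region summaries). The probes × conditions submatrix is decomposed by
Tukey median polish — alternating row- and column-median sweeps, rows
first, until the largest sweep adjustment falls below `tol` ($10^{-4}$) or
`max_iter` (10) sweeps — and the region's per-condition summary is the
overall effect plus the column effect. Probe (row) effects and residuals
are excluded, which is what makes the summary robust to individual rogue
probes: one gross outlier cell in a 5×5 block moves the summaries by less
than 0.01. Single-probe regions pass through unchanged; zero-probe regions
are flagged and excluded rather than raising an error.

## Expression and differential calls

For each condition, the distribution of candidate-region summaries is
mostly noise with an expressed upper tail. `fit_noise()` estimates the
noise location as the median and its scale, by default, from the *lower
half only*: $\hat\sigma = \mathrm{median} - Q_{0.1587}$ (for a Gaussian the
15.87th percentile lies one sigma below the median), so an expressed upper
tail cannot inflate the estimate — under 5% contamination six sigma up, the
cutoff moves by under 7%, where a naive mean + z·sd cutoff moves by over
25%. A MAD estimator is available as an alternative. The expression cutoff
is the inverse normal cumulative distribution function at `percentile`
(default 99.9%):

$$\text{threshold} = \hat\mu + \Phi^{-1}(0.999)\,\hat\sigma
                   = \hat\mu + 3.090\,\hat\sigma.$$

A region is *expressed* when it exceeds the threshold in at least one of
the conditions (the minimal reading of a single cross-condition candidate
list). Under a Gaussian null the per-condition call rate is calibrated at
$1 - \text{percentile}$.

Differential expression applies the same procedure to the sample standard
deviation (n−1 denominator) of each region's per-condition profile. The
noise model is fitted on the standard deviations of **all** candidate
regions — the bulk of which are unexpressed and supply the null
distribution — while the differential flag is restricted to the expressed
regions by default (`differential_universe`). Fitting on the expressed
subset alone would be self-defeating whenever most expressed regions really
are condition-specific. A known property of this stage: the sd of $k$
Gaussian replicates is chi-distributed, not Gaussian, so the
normal-quantile cutoff is conservative in name only — with 5 conditions its
true null exceedance is near 2% rather than 0.1%. The tests document this
with a chi-squared-derived oracle; with planted effects of +2 log2 against
a null sd an order of magnitude smaller, the miscalibration is immaterial
for recovery, but the nominal percentile should not be read as a false
discovery rate.

## Post-analysis

*Clustering.* Differential profiles are standardized per region (mean 0,
sd 1 across conditions), clustered agglomeratively (Euclidean distance,
complete linkage — R's `hclust()` default) and cut into `k = 3` groups by
default, matching the exponential / stationary / symbiosis pattern.
Group labels are deterministic (ordered by group size) so runs are
reproducible; zero-sd rows cannot be standardized and are excluded with a
warning.

*Density and hotspots.* `replicon_density()` reports regions per megabase
per replicon and chromosome/plasmid aggregates. `hotspot_scan()` slides a
window (300 kb, step 50 kb by default) and flags windows whose count
exceeds the $1-\alpha$ Poisson quantile at the replicon-wide rate — a
formalization of reading a dense stretch off a genome plot; window, step
and $\alpha$ are invented knobs and exposed as such. Because Poisson
quantiles are discrete, the realized flagging rate under uniform placement
sits at or below $\alpha$.

*Conservation.* Candidate-region sequences are scanned against relative
genomes; the per-genome best E-value (computed against the total genome
length) is tiered inclusively: strong ($E \le 10^{-5}$), weak
($E \le 10^{-3}$), none. The per-genome conservation percentage is the
share of regions in any tier.

## The synthetic study

`simulation_config()` fixes the study conditions; the defaults are the
conditions under which the acceptance checks run and are not tuned per
run:

| parameter | default | why |
|---|---|---|
| genome | 2 Mb circular chromosome + 0.5 Mb plasmid | multi-replicon rhizobial layout at desk scale |
| genes / gaps | Gamma(9, 100) lengths (≥150 bp); Exp(200 bp) gaps | ~900 bp genes, realistic IGR length spectrum |
| candidate regions | 500, of length 60–250 bp, inside IGRs | the funnel's denominator; sRNA-sized |
| expressed | 50, effect +2 log2 | clear but not caricatural induction |
| groups | exponential (conds 1–2), stationary (3), symbiosis (4–5) | three condition-specific profiles over 5 conditions |
| tiling | 60-mer probes every 13 bp, forward strand | 47 bp overlap; single-strand regular grid |
| intensity model | baseline 7, affinity sd 0.5, offsets sd 0.25, quadratic bias, noise sd 0.3 | gives the loess a smooth nonlinearity to remove |
| predictions | 1–3 copies per region, 5% substitutions, ±10 bp trims, 6 pseudo-studies, 200 decoys | literature-compilation redundancy and noise |

Probe-level log2 intensity is additive: baseline + probe affinity +
planted signal + array offset + per-array quadratic bias in the underlying
abundance + Gaussian noise; raw intensities are the power of two. All
randomness derives from the single config seed (stage-wise offsets keep
the genome, predictions and intensities independently reproducible), so a
fixed seed reproduces every output byte for byte.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: sequence-dependent probe affinity and
cross-hybridization, the irregular probe layout of a commercial design,
transcription units straddling gene boundaries, correlated (non-Gaussian)
probe noise, and partial homology structure among predictions. Recovery
rates on synthetic data are upper bounds, not forecasts, for real arrays.

At the default conditions (seed 1) the pipeline recovers all 50 planted
regions (sensitivity 1.0), holds the per-region-per-condition false-call
rate near the nominal 0.1% (0.3% observed), recovers all planted
condition-specific regions as differential, and clusters them into the
three planted groups with adjusted Rand index 1.0. These numbers are
recomputed, not quoted, by `scripts/acceptance.R` and the test suite.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere externally; BED output is
  0-based half-open. Origin-wrapping intervals on circular replicons are
  stored as `start > end` and split at the origin where a linear
  representation is needed.
* IGRs are bounded by the strand-ignored union of gene intervals; which
  feature types count is configurable (`feature_types`, default `gene`),
  since structural-RNA genes may or may not be wanted as boundaries.
* `karlin_lambda()` solves its defining equation to $<10^{-10}$ by
  bisection-safe root finding and refuses schemes with non-negative
  expected score.
* Median polish convergence is the largest absolute sweep adjustment;
  stopping after `max_iter` without convergence is reported, not an error.
* `fit_noise()` requires ≥20 values and a strictly positive scale; ties
  and constant data are errors rather than silent zero-width thresholds.
* Clustering ties in group sizes are broken by first occurrence, making
  labels order-invariant.
* Pipeline problem sizes (2.5 Mb genome, ~190k probes, ~1200 predictions,
  500 regions) are the package's chosen desk-scale defaults; a full run
  completes in about a minute and a half on one core.

## Limitations

The package reimplements the analysis, not the laboratory study: array
manufacture, hybridization chemistry, RNA isolation and wet-lab validation
are out of scope, as are Rfam/RibEx annotation queries and the biological
classification of detected regions. The aligner's defaults emulate a
classic nucleotide search but are not a byte-level BLAST reimplementation
(no length adjustment, no two-hit seeding, single K constant), so E-values
agree in order of magnitude, not in the last digit. With one array per
condition (pooled RNA), there is no replicate-level variance model — the
robust noise threshold is the significance machinery, and the nominal
percentile is a calibration statement about the per-condition null, not an
FDR.
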