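---
title: "Methods: consensus CNV discovery and cis-eQTL mapping from tiling aCGH"
author: "cghcnv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus CNV discovery and cis-eQTL mapping from tiling aCGH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and numerical choices
behind `cghcnv`, in the spirit of the methods sections of segmentation
and differential-analysis packages. Nothing here reports an empirical
result; all quantitative claims are checked by the test suite or
recomputed by `scripts/acceptance.R`.

## The measurement model

A tiling aCGH array measures, for each of millions of genomic probes, a
log2 intensity ratio of a test genome against a reference:
approximately 0 for copy-neutral probes, shifted up for duplications
and down for deletions. Realistic expectations for shift magnitudes
are log2(3/2) ≈ +0.58 for a single-copy gain and about −1 for a
heterozygous deletion against a diploid reference; these are the
generator defaults (`effect_gain`, `effect_loss`), configurable because
real shifts are compressed by hybridization saturation.

Two systematic artifacts dominate: a smooth dependence of the measured
ratio on probe GC content, and "waves" — slowly varying spatial trends
along chromosomes unrelated to copy number. The simulator
(`simulate_acgh`) adds exactly these components: a quadratic GC term
`β₁·GC + β₂·GC²`, a sinusoidal wave with per-(array, chromosome) random
phase, and i.i.d. Gaussian probe noise. The sinusoid is deliberately
the *simplest* signal a local-regression correction must remove; real
waves are less regular, so the wave-removal figures measured on
simulations are an upper bound on what to expect on real arrays.

## Normalization

**GC residualization** (`gc_residualize`) fits, per array,
`log2(R_i) = α + β₁·GC_i + β₂·GC_i² + ε_i` by OLS and subtracts the
fitted values, intercept included. Refitting the model on the output
gives coefficients that vanish to numerical precision (a tested
invariant), and the operation is idempotent. Probes with missing
values are excluded from the fit and restored as missing. A constant
GC profile makes the design rank deficient and is an error, not a
silent fallback.

**Wave correction** (`wave_correct`) fits a locally linear LOESS model
of log2-ratio on probe position per chromosome and array (tricube
weights, one robustness iteration via the symmetric family) and
subtracts the trend. The window is parameterized as an **absolute
number of probes per local fit** rather than a proportion, so the
genomic bandwidth does not vary with chromosome size. Chromosomes
shorter than the window fall back to median subtraction (logged).
LOESS degree, robustness iterations and the interpolation surface are
implementation choices the source method leaves open; they are fixed
here (degree 1, one robust iteration) and noted as configurable in
principle.

**Span selection** (`select_wave_span`) chooses the window by a
signal-to-noise criterion: for every probe inside a CNV test set,
`SNR_i = |log2(R_i)| / σ_Ci`, with `σ_Ci` the standard deviation of
*all* probes on that chromosome — CNV probes are not masked, a
conservative choice that slightly deflates SNR but follows the
definition's plain reading. Each array is summarized by its mean SNR
over test-set probes; each candidate span by the median across arrays
of the relative improvement after correction. Ties go to the smaller
span; if every span degrades the median SNR, the sentinel `NA` ("no
correction") is returned together with the full table. The test set
itself (`build_snr_test_set`) is built the way the final calls are:
all three callers on GC-normalized data, consensus, and retention of
regions seen in ≥ 2 individuals. The default candidate grid
{1000, 2000, 4000, 8000, 16000} probes brackets the span this class of
arrays typically selects (4000 probes).

## The three segmentation stand-ins

The scientific design point is *consensus*: three inherently different
algorithms so that method-specific errors do not survive the
two-of-three vote. The three callers implemented here are documented
stand-ins that keep the published parameter names, defaults and filter
semantics, but do not reproduce the internals of the original programs
(sparse Bayesian learning, the exact max-t permutation distribution, or
the original window model):

* `call_gada_like(alpha = 0.2, T = 4.5, minseglen = 5)` seeds a dense
  set of candidate breakpoints wherever the standardized local jump
  (difference of the `minseglen`-probe means flanking a position)
  exceeds `qnorm(1 − alpha/2)` at a local maximum, then removes
  breakpoints by **backward elimination** while any between-segment
  t-statistic is below `T`. This mirrors the candidate-generation +
  backward-elimination architecture of the genome-alteration detection
  approach it stands in for; `alpha` acts as the sparsity dial.
* `call_cbs_like(minseglen = 5, undo_sd = 3, undo_prune = 0.05,
  smooth = TRUE)` performs recursive **arc-based binary segmentation**:
  within a segment, the maximal standardized contrast of a candidate
  arc against the rest (scanned over all positions and a
  dense-then-geometric width grid) is accepted if fewer than 1% of
  ≥ 100 within-segment permutations reach it; accepted arcs are refined
  by coordinate ascent and split the segment in three. Splits are then
  undone when adjacent means differ by less than `undo_sd` noise
  units, and breakpoints whose removal grows the within-segment SSE by
  less than `undo_prune` are pruned. Prior outlier smoothing shrinks
  single-probe spikes (> 3 sd from the running 3-probe median), so
  isolated outliers never seed calls. The permutation arc-scan is the
  computational hot spot and is implemented in C++ (`src/cbs_scan.cpp`),
  as segmentation packages in this field generally do.
* `call_window_like(r = 20, T = 4, m = 5, a = 2.1, P = 0.001)` scores
  sliding windows of `r` probes by their standardized mean, merges
  overlapping same-sign windows above `T`, refines candidate edges by
  the same arc statistic, and assigns each region a **carrier
  probability**: the posterior of a two-component Gaussian contrast in
  which non-carrier probes are N(0, s²) and carrier probes
  N(0, (a·s)²), with prior carrier probability `P`. The published
  window method's parameter semantics are not documented in detail;
  the mapping above (window size, seed threshold, minimum probes,
  carrier scale, prior) is this package's stated interpretation, not a
  reconstruction.

**Noise scale.** All three callers estimate the per-chromosome noise sd
from median absolute first differences scaled for Gaussian consistency
(`median|Δy| / (√2 · Φ⁻¹(3/4))`); breakpoints contribute only a handful
of outlying differences, so the estimate is robust to the CNVs
themselves. Exact zero estimates on noise-free input are floored at
1e−10 so that noise-free limits remain well defined.

**Call filters** (`apply_call_filters`). For the two segment-mean
callers the z-score of a call is its mean log2-ratio centred by the
chromosome median and scaled by 1.4826 × MAD of all chromosome probes —
a robust basis chosen because the published filter does not specify its
denominator; calls are kept when |z| > 1.5 (strict). Window calls
require carrier probability ≥ 0.8 (inclusive — the boundary case is
tested). A minimum of 5 probes per call is re-enforced for all
methods.

## Consensus, CNVRs, genotypes, structure

Overlap everywhere means *any shared base pair* (single linkage, no
reciprocal-overlap fraction — the source rule says "overlapping"
without a fraction). Intervals are 0-based half-open throughout;
touching intervals share no base and do not merge (enforced via
`IRanges::reduce(min.gapwidth = 0)` and guarded by a randomized
transitive-closure oracle test).

* `consensus_per_individual`: per individual, calls across methods are
  grouped by single-linkage overlap; groups with ≥ 2 distinct methods
  and one state become one consensus CNV spanning the union; groups
  mixing gain and loss are dropped entirely.
* `build_cnvrs`: consensus CNVs merge across individuals into CNVRs
  (union spans, carrier states recorded). An individual contributing
  more than one CNV to a region marks it *complex*. A CNVR
  "has deletions" when at least one carrier state is a loss — the
  convention used when counting deletion regions for structure
  analysis.
* `filter_cnvrs` removes complex loci, sex-chromosome loci, and loci
  within 250 kb of any inter-probe gap larger than 500 kb. The gap
  rule's source phrasing ("larger than 500 kb + − 250 kb") is
  ambiguous; it is read here as a ±250 kb exclusion margin around
  > 500 kb gaps, and both numbers are arguments. Every removed CNVR is
  logged with its reason, and kept + removed always reconciles with the
  input (a tested invariant).
* `quantitative_genotypes`: the genotype of individual *i* at a CNVR is
  the median of *i*'s normalized log2-ratios over the CNVR probes, for
  **all** individuals (non-carriers hover near zero). Medians of even
  counts take the mean of the middle two. The whole matrix matches a
  probe-by-probe oracle exactly in tests.
* `population_structure`: PCA of the individuals × CNVRs matrix,
  column-centred, covariance convention (divisor n). It is computed by
  SVD rather than `princomp` because the latter refuses n < p, which is
  the normal shape here (few individuals, many CNVRs); equality with
  `princomp` on n > p inputs is a unit test. Clustering is
  average-linkage (a choice; the source does not specify linkage) on
  1 − Pearson correlation between individuals' genotype vectors, with
  Newick export via `ape`.

## The cis-eQTL stage

Eligibility: non-complex CNVRs carried by ≥ 2 individuals whose nearest
boundary lies within 1 Mb of the gene's TSS (inclusive). Distance uses
the **boundary** for eligibility but the **midpoint**, strand-oriented,
for signed distance summaries — eligibility follows the window's plain
wording, while a single signed value per pair is needed for
TSS-distance profiles. Both conventions are configurable.

The association model is `E_it = α + β₁·C_i + β₂·G_it + ε_it`, with
`C_i` the quantitative genotype and `G_it` the individual's score on
the first principal component of the gene-centred expression matrix of
the same tissue. The PC1 covariate absorbs global transcriptome shifts
(batch, stratification, physiological state); its sign is fixed by
positive correlation with per-individual mean expression, an arbitrary
but reproducible convention. Note the covariate can only *help* when
the confounder correlates with genotype structure; the simulator
therefore accepts an explicit population-aligned confounder for
stratification experiments in addition to the default i.i.d. one.

Multiple testing is two-step: (1) **local permutations** — individual
labels of the expression vector are permuted (default 1000 times,
shared permutation set per tissue), the minimum nominal p across the
gene's cis CNVRs is recomputed each time, and the gene-level p-value is
`(1 + #{min p_perm ≤ min p_obs}) / (n_perm + 1)`, bounded below by
1/(n_perm+1). Direct permutation with a fixed count is the contract —
simple, exactly specifiable, and reproducible — rather than an
adaptive/beta-approximation scheme. (2) **Storey q-values per
tissue** with π₀ estimated at a single λ = 0.5 (robust at small gene
counts; a grid estimator adds noise at a few hundred genes), clamped to
(0, 1] and falling back to π₀ = 1 (Benjamini–Hochberg) when no p-value
exceeds λ. Significance is q < 0.10.

**Region scan** (`region_secondary_scan`): significant eQTLs of one
tissue whose 1 Mb TSS windows overlap collapse into non-overlapping
regions (single linkage; the source reports non-overlapping regions
without a construction rule, so the rule is explicit here and the lead
is the smallest permutation p). All genes within 1 Mb of the lead TSS
are tested against the lead CNVR with the same model; per-region
Bonferroni (`min(1, m·p)` with m the genes tested, lead included by
default) defines significance at 0.05, and each association records
whether its sign matches the lead's.

**Summaries** (`eqtl_summaries`): per tissue, a two-sided Wilcoxon
rank-sum test (normal approximation with tie correction) of eQTL-gene
mean expression against all other genes; across tissues, an exact
two-sided binomial test of upstream vs downstream CNVR placement; and
the signed TSS-distance table.

## The synthetic study

`make_probe_set` tiles chromosomes at a jittered target spacing
(default 598 bp median, the density of the array class this package
addresses) with an AR(1) GC profile (correlation length 50 kb,
isochore scale) clamped to [0.2, 0.8]. `simulate_cnv_truth` plants
loci with log-normal lengths (median 8.4 kb) clamped to 2.3–693 kb —
the size range such studies report — with 60% duplications. Carriers
follow a founder + binomial-sharing model per population
(`sharing = 0` makes every CNV private; `sharing = 1` fixes it in the
population), and a fraction of duplication loci recur independently
across populations (default 0.25), reflecting the recurrent-mutation
asymmetry that makes deletions better population markers than
duplications. Allele-frequency spectra per population are deliberately
exposed as configuration rather than fixed: the source material gives
no values, so the defaults are one realistic choice, not an estimate.
Loci that cannot cover five probes are skipped with a warning, never
shrunk. All randomness flows from one master seed through per-stage
substreams.

`simulate_expression` generates
`E_it = α_g + β·C_i + γ_g·u_i + ε_it`, with a per-individual
confounder `u` entering every gene through its own N(0, 1) loading so
that expression PC1 captures it, and records every planted non-zero β
per tissue.

What the simulation does *not* emulate: probe-to-probe correlated
noise, dye and spatial effects, saturation compression of large
amplifications, multi-allelic copy states, and irregular (non-sinusoidal)
waves. Passing tests therefore demonstrate algorithmic correctness
under the stated generative model, not performance on any particular
real array platform.

## Problem sizes and numerical conventions

The test suite and acceptance script run at desk scale, chosen as the
package's own trade-off between statistical resolution and turnaround:
caller recovery uses 100 Monte-Carlo seeds on 2000-probe chromosomes
(false-call rates are normalized per 50 kprobes); normalization checks
use ~50k probes; the end-to-end acceptance pipeline uses two 12 Mb
chromosomes (~40k probes), 16 individuals in 4 populations, 300 genes
and 3 tissues with 1000 permutations. Key numeric conventions:
degenerate noise estimates floored at 1e−10; PCA via SVD with scores
`U·D`; q-value step-up monotonicity enforced by a reverse cumulative
minimum; ties in span selection resolved toward the smaller span; all
breakpoint intervals half-open so a probe belongs to at most one
segment per method.

## Known limitations

* The three callers are faithful to the published *parameters and
  filters* but are stand-ins; absolute sensitivities will differ from
  the original programs, which is why all recovery guarantees are
  stated (and tested) for the stand-ins themselves.
* Only two copy-number states (gain/loss vs reference) are modelled; no
  integer copy numbers, no sex chromosomes, no trans-eQTLs, no
  multi-variant conditional models.
* Storey's π₀ at a single λ is slightly conservative when the true
  non-null fraction is large.
* With dense CNVR landscapes, gene-level min-p permutation correction
  pays a penalty proportional to the number of cis CNVRs per gene;
  power figures assume the simulated landscape density.
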