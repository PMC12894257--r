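---
title: "Methods: from peak coordinates to molecular signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from peak coordinates to molecular signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`gmtx` chains five analyses: a coordinate-based meta-analysis (CBMA) of
gray-matter findings, expression-atlas preprocessing, spatially
constrained gene-category enrichment, specificity and network
enrichment, and receptor-map correlation. This vignette documents the
models, the tunable parameters, the synthetic-data generator that stands
in for real inputs, and the numerical and design choices a reader would
otherwise have to reverse-engineer from the code. It states no result
that the test suite and `scripts/acceptance.R` do not themselves
compute.

## 1. Coordinate-based meta-analysis

### Model

Studies report only peak coordinates and peak statistics, so per-study
effect maps must be reconstructed before pooling. A reported t becomes a
small-sample-corrected standardized mean difference
`d = J · t · sqrt(1/n1 + 1/n2)` with `J = 1 − 3/(4·df − 1)`, and its
sampling variance is the standard
`var(d) = (n1+n2)/(n1·n2) + d²/(2(n1+n2))`. Each peak is spread with an
isotropic Gaussian kernel parameterized by its full width at half
maximum (`fwhm`, default 20 mm — the conventional CBMA kernel size),
truncated at `2·fwhm`. Where kernels overlap, the contribution with the
larger magnitude wins; summing is the documented alternative but
inflates effects when a study reports adjacent peaks of the same
region. Anisotropic, tissue-informed kernels would require a
tissue-correlation template we do not ship; the kernel function is a
single internal seam (`kernel_footprint`) if one wants to replace it.
Voxels no kernel reaches carry d = 0 with the study's full variance —
the study is treated as a null observation there, which is the
assumption that reported peaks are complete.

Pooling is voxelwise DerSimonian–Laird: fixed-effects weights give
Cochran's Q, `tau² = max(0, (Q − (k−1))/C)`, and the pooled mean,
standard error and z use weights `1/(v_i + tau²)`. The implementation is
checked to 1e-10 against a frozen closed-form fixture and, in the test
suite, against `metafor::rma(method = "DL")`.

### Inference and diagnostics

The voxel-level null relocates every study's peaks uniformly within the
mask (keeping their effect sizes) and re-pools; the pooled null |z|
values over a configurable number of iterations (`n_null`, default 200)
define the voxel threshold at `voxel_p` (default 0.005). Suprathreshold
voxels form 26-connected components, separately for increases and
decreases; clusters must reach peak `|z| >= peak_z` (default 1) and
`extent` voxels (default 50; the heterogeneity analysis uses 10). The
order of the two height rules is not externally specified; we threshold
voxels first and then apply the peak-height filter per cluster.

A cluster's *location* is reported as its |z|-weighted center of mass;
the argmax voxel is kept in separate columns. Under 8 mm peak jitter the
argmax wanders on the kernel-wide plateau (its localization error
exceeds 10 mm in roughly one run in eight at the default design), while
the centroid is stable; the acceptance suite measures localization with
the centroid.

Jackknife survival re-pools with each study left out and counts runs
reproducing an overlapping same-sign cluster, reusing the main run's
null threshold so that survival reflects the data rather than
re-estimation noise. Heterogeneity uses voxelwise Q against
chi-square(k−1) expressed as an equivalent z. Egger's test regresses
`d/SE` on `1/SE` at the cluster peak over the studies whose kernel
reaches it, reporting the two-sided intercept p; fewer than three
contributing studies yields NA.

## 2. Expression-atlas preprocessing

The pipeline order is fixed: intensity filter → probe selection → scaled
robust sigmoid (SRS) normalization → differential-stability (DS) filter
→ mask restriction. Parameters: minimum above-background fraction 0.5;
minimum probe–RNA-seq correlation 0.2 with the max-r probe representing
each gene (without an RNA-seq reference the max-variance probe is used,
with a loud warning, because the correlation rule cannot run); DS
retention fraction 0.5, with 0.4 and 0.6 exercised by
`run_ds_sensitivity()`.

SRS maps a vector through
`1/(1 + exp(−(x − median)/(IQR/1.35)))` and min–max rescales to [0, 1];
the 1.35 makes IQR/1.35 approximate the SD under normality, so the
sigmoid has a unit-like scale while staying outlier-robust. It is
applied within-sample (across genes) and then within-gene (across
samples); each pass is monotone in its input vector. Zero-IQR vectors
map to a constant 0.5.

DS is the mean over donor pairs of the correlation between a gene's
regional mean-expression profiles; we use Spearman (robust to per-donor
monotone distortion; Pearson is available by argument). Real atlas
region annotations are not shipped, so regions are k-means parcels of
the sample coordinates (default 30). Donor pairs sharing fewer than two
regions are skipped; a zero-variance gene contributes 0 for that pair.
An optional left-hemisphere-only switch reflects the common practice
when right-hemisphere coverage is limited to a minority of donors.

## 3. Gene scores and ensemble category enrichment

The z-map is averaged within spheres of `radius` 3 mm centered on each
tissue sample (mean over in-mask voxel centers within the radius;
samples reaching no in-mask voxel are dropped and logged — on coarse
synthetic lattices this prunes a substantial fraction, which is why the
generators place enough samples). A gene score is the Pearson
correlation of a gene's expression with that sphere vector;
constant-expression genes score 0 with a warning.

Categories are flat gene sets filtered to 10–200 members among retained
genes. The observed category score is the mean member gene score. The
null recomputes sphere vectors and all gene scores for each of `n`
surrogate maps and takes the same category means, so it inherits both
the map's spatial autocorrelation and the category's member
co-expression (the suite asserts that a coherent and an independent
category of equal size get different null widths). The two-sided p is
`(1 + #{|null − mean| ≥ |obs − mean|})/(n + 1)`, centered on the null
mean because gene-score nulls are not mean-zero under spatial
autocorrelation; p is never 0. Ensembles below 100 maps are refused
outside explicit opt-in, as the p resolution becomes meaningless.
Production ensembles use 10,000 maps; the tests use 1,000 where
calibration is measured and less where only determinism or plumbing is
at stake.

### Surrogate maps

Surrogates must randomize topography while preserving the value
distribution and spatial autocorrelation. Each surrogate is built by
smoothing independent permutations of the map at `n_scales` (default 8)
candidate length scales spanning half a voxel to a quarter of the mask
extent, adding a white-noise nugget component, and fitting nonnegative
mixture weights so that the mixture's variogram — the components are
independent, so their variograms add — matches the empirical variogram
by least squares over 25 equal-count distance bins (pair distances up to
the median, from a 300-voxel subsample). The mixture is then rank-
remapped to the original values. A single-scale smoother cannot match
maps whose autocorrelation lives on several scales at once; the mixture
markedly tightens the short-range fit on the synthetic alteration maps,
and the fidelity criterion (mean relative bin deviation < 0.15) is
measured by the acceptance suite. On lattices the smoothing is separable Gaussian
convolution normalized by the smoothed mask (fast, exact at the
boundary); for scattered data a k-nearest-neighbor kernel smoother is
used instead. White-noise input puts all weight on the nugget and
degenerates to plain permutation, as it should.

One caveat we document rather than hide: variogram matching constrains
second-order isotropic structure only. For strongly non-Gaussian maps —
a few compact blobs on a smooth background, which is exactly what a
kernel-reconstructed meta-analytic map looks like — the observed map
couples with smooth expression fields slightly more than its surrogates
do, and the category test becomes mildly anticonservative (measured
rejection around 0.05–0.10 at nominal 0.05 across generator seeds,
versus 0.04–0.05 on stationary Gaussian fields). This is a property of
the surrogate-null method itself, not of this implementation; the
acceptance suite measures calibration under the designed study
conditions.

## 4. Specificity enrichment and hubs

Fisher's exact test (two-sided, the tools' convention) per panel label
on the 2×2 table of candidate × label membership over the background
universe, with Benjamini–Hochberg q across the panel and significance at
q < 0.05. The background defaults to the genes surviving preprocessing,
since candidates are drawn from it. Hub detection deduplicates edges
(max score per pair), drops self-loops and edges below confidence 0.9,
and takes the top `ceiling(0.10 · n)` nodes by degree among nodes with
at least one retained edge, ties broken by (degree, lexicographic id) so
the report is deterministic.

## 5. Receptor-map correlation

Pearson r between the GM map and each panel map over in-mask voxels
(or over parcel means; a cubic-block parcellation is provided for
synthetic runs). The null correlates surrogates *of the GM map* with
each receptor map — one ensemble serves the whole panel, which is also
why 20-seed null-calibration checks can share it. Two-sided permutation
p with the add-one convention, BH-FDR and Bonferroni across the panel
(m = panel size as supplied, not hard-coded), significance flagged at
q < 0.01. The suite asserts that the spatial null is strictly wider than
the naive `1/sqrt(n−1)` parametric null on smooth maps — the reason
spatial correction exists.

## 6. The synthetic-data generator

The generator defines the study conditions: 15 studies with group sizes
uniform on 13–67, two planted loci at MNI (22, −2, −32) and
(−32, −6, −4) with d = ±0.8, per-study miss probability 0.1, 8 mm
isotropic peak jitter, and reported t drawn consistently with d and the
group sizes via `t = d·sqrt(n1·n2/(n1+n2))` with sampling noise at the
d-variance. The latent alteration pattern that genes and receptor maps
track is the pair of Gaussian bumps (FWHM 20 mm) plus a weak smooth
background field (0.3 of the peak amplitude, 20 mm scale, deterministic
per seed). The background exists because a map that is zero almost
everywhere has a far heavier-tailed value distribution than any real
statistical brain map, which makes the sigmoid normalization saturate
the informative tail; real maps vary continuously everywhere.

The atlas emulates six donors (two covering the right hemisphere), 120+
samples per donor at jittered in-mask voxel centers, three probes per
gene (one faithful; degraded duplicates, a fraction planted below
background intensity or as pure noise to exercise both probe filters),
an RNA-seq reference correlated with the faithful probes, and Gaussian
measurement noise (sd 0.3). Signal genes mix the standardized pattern
with a spatially autocorrelated field (15 mm squared-exponential); the
mixing weight is inflated by `sqrt(1 + noise_sd²)` so the *measured*
faithful probe realizes the planted correlation. Null genes are
autocorrelated fields, 60% donor-specific (low DS) and 40% shared
across donors (high DS), so the DS filter has signal to act on.
Receptor maps mix the standardized pattern with an autocorrelated field
residualized against it, so the planted in-mask correlation is realized
exactly — smooth fields over a brain-sized domain carry so few
effective degrees of freedom that, without residualization, realized
correlations scatter around the target by more than the recovery
tolerances downstream.

What the generator does not emulate: scanner artifacts and site
effects, donor demographics, hemispheric asymmetry beyond coverage
flags, anisotropic tissue structure, ontology structure among
categories (sets are flat and independent), and degree-correlated edge
confidence. Passing tests therefore show that the pipeline recovers the
statistical structure it models, not that it is robust to everything
real data do.

## 7. Problem sizes and numerical choices

Tests and the acceptance script run on an ellipsoidal mask (semi-axes
70, 85, 65 mm) at 4 mm (CBMA; ~25k voxels) or 6 mm (transcriptomics and
receptors; ~7.5k voxels), with 200-iteration relocation nulls, 1,000-map
surrogate ensembles where calibration or detection is measured, and a
reduced end-to-end demo for bit-reproducibility; these sizes are the
package's chosen desk-scale study conditions. Other numerics: world
coordinates are RAS+ mm with 0-based voxel indices and nearest-center
peak assignment; the Talairach conversion is a single fixed affine (the
piecewise refinement is out of scope and documented as approximate);
z→t and p→t conversions go through log-space tail quantiles to keep
precision for extreme peaks; empirical variogram bins are equal-count so
none is empty; all permutation p-values use the add-one convention; and
every stochastic stage derives its seed from one master seed via fixed
per-stage offsets, so `run_demo()` is bit-reproducible (checked by
checksum).

## 8. Known limitations

The kernel is isotropic; real tissue-informed CBMA kernels differ near
tissue boundaries. Peaks lacking a reported statistic are excluded
rather than imputed. Covariates (age, illness duration) are carried but
no meta-regression is offered. The surrogate null is approximate for
non-Gaussian maps (see §3). The specificity sets and interaction edges
are consumed as given; building them from raw atlases or databases is
out of scope. Real-data counts (sample or gene totals of any particular
atlas release) are not reproduced — they depend on the upstream
resources, not on this implementation.
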