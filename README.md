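# gmtx — gray-matter meta-analysis and its molecular signatures

`gmtx` implements, as a tested R pipeline, the inference chain that links
coordinate-based meta-analysis (CBMA) of voxel-based morphometry findings
to molecular brain maps: per-gene spatial correlation with a donor-based
expression atlas, ensemble gene-category enrichment against spatially
constrained nulls, tissue/cell-type specificity enrichment, hub detection
in confidence-scored interaction networks, and spatially corrected
correlation with receptor/transporter maps. It is written for
neuroimaging researchers who want each stage of that chain as an
inspectable, unit-tested function rather than a chain of web tools, and
it ships a synthetic-data generator that emulates every input with known
ground truth, so the whole pipeline can be exercised and calibrated
without any external download.

## The models at the core

**CBMA.** Each study reports peak coordinates and peak statistics
(t, z or p; z and p are converted to t by quantile matching). A peak t
becomes a Hedges-corrected effect size `d = J · t · sqrt(1/n1 + 1/n2)`
and is spread over the brain with an isotropic Gaussian kernel
(FWHM 20 mm, truncated at 2·FWHM; overlapping kernels resolve by signed
maximum magnitude). Studies are pooled voxelwise with the
DerSimonian–Laird random-effects model: weights `1/(v_i + tau^2)` with
`tau^2` from Cochran's Q truncated at zero, giving a pooled z-map.
Voxel-level significance comes from a peak-relocation permutation null
(each study's peaks relocated uniformly within the gray-matter mask and
re-pooled); clusters are 26-connected components passing `p < 0.005`,
peak `|z| >= 1` and extent `>= 50` voxels, with leave-one-study-out
jackknife survival, Cochran-Q heterogeneity clusters (extent 10) and
Egger regression (`d/SE ~ 1/SE`, intercept test) as diagnostics.

**Imaging transcriptomics.** The expression atlas is reduced to a
sample-by-gene matrix by intensity filtering (probes above background in
at least 50% of samples), RNA-seq-guided probe selection (drop probes
with `r < 0.2`, keep the max-r probe per gene), scaled robust sigmoid
normalization `y = 1/(1 + exp(-(x - median)/(IQR/1.35)))` rescaled to
[0, 1] (within-sample, then within-gene), differential-stability
filtering (mean inter-donor Spearman correlation of regional profiles;
top 50% retained, 40%/60% as sensitivity), and restriction to the
analysis mask. A *gene score* is the Pearson correlation between a
gene's expression across tissue samples and the z-map averaged in 3 mm
spheres at those samples. Category enrichment compares each category's
mean gene score against a null obtained by recomputing all gene scores
on variogram-matched surrogate maps — permutations of the z-map smoothed
at several length scales and mixed by nonnegative least squares so the
surrogate variogram matches the empirical one, then rank-remapped to the
original value distribution.

**Specificity, hubs, neurotransmitters.** Specificity enrichment is
Fisher's exact test per label with Benjamini–Hochberg FDR. Hub genes are
the top 10% of nodes by degree after removing interaction edges below
confidence 0.9. Receptor/transporter maps are correlated with the GM map
voxelwise (Pearson), with two-sided permutation p-values from the same
surrogate machinery, FDR and Bonferroni control across the panel.

## Worked example

Simulate a 15-study meta-analysis with one planted gray-matter increase
(d = +0.8 at MNI 22, −2, −32) and one decrease (d = −0.8 at −32, −6,
−4), 8 mm peak jitter, and run the full CBMA at the standard thresholds:

```r
library(gmtx)
grid    <- ellipsoid_mask(make_grid(6))      # 6 mm synthetic GM mask
truth   <- ground_truth(seed = 1)
studies <- simulate_study_set(truth)         # 15 studies, n in 13..67
meta    <- run_cbma(studies, grid, n_null = 200, seed = 11)
meta$clusters[, c("x", "y", "z", "peak_z", "extent", "p",
                  "jackknife", "egger_p")]
```

```
        x       y        z  peak_z extent       p jackknife egger_p
1 -28.361 -2.3610  -4.0477 -4.7469    141 6.6e-07     14/14  0.3308
2  22.079  1.9522 -31.1204  4.3113    169 6.6e-07     14/14  0.9994
```

Both planted loci are recovered with the right sign: the decrease
cluster centers 5.1 mm from the planted putamen locus and the increase
cluster 4.0 mm from the planted medial-temporal locus (`x, y, z` is the
|z|-weighted cluster centroid; `px, py, pz` hold the peak voxel). Both
survive all 14 leave-one-out runs (one simulated study reported neither
locus and dropped out), and Egger's test finds no small-study bias —
none was planted.

The numbered scripts under `analysis/` continue from here: they write
all synthetic inputs to `results/inputs/` (stage 01), run the CBMA
(02), preprocess the atlas to a 1020-sample × 500-gene matrix (03),
compute gene scores and category enrichment — detecting all 5 planted
categories (04), rank the planted specificity label first and recover
all 10 planted hubs (05), correlate the receptor panel (06), and check
stability across differential-stability cutoffs (07). `run_demo(seed)`
chains the same stages in one call and writes a ground-truth recovery
report.

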