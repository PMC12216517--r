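---
title: "Structural modeling magnitude and orientation radiomics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural modeling magnitude and orientation radiomics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

After neoadjuvant therapy for locally advanced rectal cancer, deciding
whether a tumor has regressed enough for non-operative management requires
judging how the rectal wall has structurally changed. Radiologic stage
agrees with pathologic stage only slightly better than chance, so this
package implements an image-based surrogate: the wall of a treated patient
is compared against a canonical *non-diseased* atlas of the same organ, and
the per-voxel displacement needed to carry the atlas anatomy onto the
patient is summarized into a compact descriptor.

The StODeO (STructural mOdeling magnituDE and Orientation) descriptor has
two parts, both computed in atlas space over the annotated wall region:

* **Magnitude** `F_m`: the per-voxel Euclidean norm
  `D(c') = sqrt(dx^2 + dy^2 + dz^2)` of the displacement vector, summarized
  by its median, standard deviation, skewness and excess kurtosis (4
  values). Large and variable magnitudes indicate pronounced structural
  change relative to healthy anatomy.
* **Orientation** `F_o`: the angle
  `theta(c') = arccos(v' . v0 / (|v'||v0|))` between each displacement `v'`
  and the vector `v0` from the voxel to the lumen centroid, quantized into
  five bins (0-20, 20-80, 80-100, 100-160, 160-180 degrees) and normalized
  (5 values). Mass near 0 degrees means displacement *toward* the lumen
  (shrinkage-like), mass near 180 degrees means *outward* displacement
  (growth into the surrounding fat). Orientations are computed only on the
  wall region exhibiting the largest displacements, isolated by
  Markov-random-field clustering of the magnitude map (6 classes, 8
  iterations, spatial potential 0.5).

Traditional texture radiomics (Gabor, Sobel gradient, CoLlAGe) complement
the structural descriptor, and the combined feature set feeds a supervised
(mRMR + LDA/QDA/RF, repeated stratified cross-validation) and unsupervised
(t-SNE + consensus clustering) evaluation, plus Spearman/positive-FDR
correlation against immune-cell counts.

## Conventions this package fixes

Several numerical conventions are not pinned down by the published method;
the package fixes them as follows and tests against them:

* **Displacement sign.** The displacement at atlas voxel `c'` is the
  patient-space position of that material point minus its atlas-space
  position. Outward tumor growth therefore yields vectors pointing away
  from the lumen (bin 5), inward displacement yields bin-1 mass. This is
  the only orientation consistent with the stated reading of the
  inward/outward bins.
* **Bin edges.** The published edges 0-20-80-100-160-180 do not say where
  the boundaries fall. The stated invariance — negating every vector must
  exchange bin k with bin 6-k *exactly* — combined with the convention that
  20 degrees falls in bin 2 forces the unique assignment
  `[0,20), [20,80), [80,100], (100,160], (160,180]`.
* **Lumen centroid.** For a tubular organ the inward/outward axis is
  in-plane, so the reference centroid is the lumen centroid of each voxel's
  own axial section (a global 3-D centroid would tilt angles toward 90
  degrees for voxels far from the mid-section; the option is retained as
  `centroid_mode = "volume"`).
* **Moment estimators.** Skewness and kurtosis are moment-based (biased)
  sample statistics, kurtosis as excess kurtosis; constant samples return 0
  by convention. Standard deviation uses the n-1 denominator.
* **MRF degeneracy.** Running 6 magnitude classes over a field with fewer
  true levels splits each level across several classes. Classes whose mean
  magnitudes differ by less than `merge_gap` (default 0.2) times the
  magnitude SD are merged before the top class is selected, which makes the
  piecewise-constant case well defined without altering behavior on
  genuinely multi-level data.

## The registration engine

No registration library exists in the target environment, so the engine is
implemented in the package (C++ core): staged rigid, affine and cubic
b-spline free-form deformation, multi-resolution with a Gaussian
(anti-aliased) pyramid, center-of-mass initialization from the wall masks,
and normalized mutual information (32 bins, Parzen-style partial-volume
histogram) or SSD as the similarity. The b-spline stage combines
synchronized gradient-ascent passes — using the exact analytic gradient of
the Parzen-binned metric with respect to every control coefficient,
validated against finite differences — with greedy per-control refinement,
under a bending-energy penalty on the control lattice
(`bending_lambda`, per mm^2) that keeps the field smooth and invertible.
After each deformable stage the global translation is re-refined: the
global stages otherwise inherit a bias picked up while the structures still
mismatch. Transform inversion uses damped fixed-point iteration with the
affine part inverted in closed form; voxels with non-positive Jacobian
determinant are excluded from the descriptor ROI and counted.

Two practical lessons from the phantom experiments are worth recording.
First, mutual information is nearly blind on radially symmetric structures
whose atlas and patient appearances are uncorrelated: any radius-to-radius
remapping preserves the functional intensity relation, so the NMI landscape
has almost no useful gradient. Real anatomy is irregular enough that NMI
works there, which is exactly why the published method can use it; for
synthetic tubes the deformable stage instead runs on smoothed signed
distance transforms of the wall masks with SSD
(`channel = "structural"` in `register_atlas_to_patient()`), the same
structure-not-appearance design used for atlas construction. Second, a
straight tube is invariant under axial translation and axial rotation, so
those parameters are pure gauge freedoms along which any optimizer drifts,
polluting the extracted field; the phantom pipeline therefore restricts the
transform to in-plane motion without rotation (`axes`, `rotations` in
`reg_control()`), and the phantom generator gives every tube a mid-length
wall-thickness bump that anchors axial correspondence.

## Atlas construction

Subjects are aligned to the median-wall-volume subject first, then to the
evolving mean template (a groupwise surrogate), with the registration
driven on wall signed-distance channels: the atlas is structural — it
represents wall and lumen anatomy rather than intensity appearance, which
also sidesteps appearance differences across the healthy cohort. The
template is the mean aligned intensity volume; `wall_prob` and `lumen_prob`
are voxelwise label frequencies. Because per-subject registration drift
accumulates into the average, the canonical space is re-anchored after
averaging so the wall-probability centroid coincides with the cohort-mean
wall centroid. Convergence is declared when the mean absolute template
change falls below 1e-3 of the intensity range (at most 5 iterations).

## What the phantom generator emulates — and what it does not

`make_tube()` builds a hollow tube (bright annular wall, dark lumen,
intermediate background) at the working resolution 0.781 x 0.781 x 4 mm on
a 96 x 96 x 24 grid, radii 8/12 mm — wall thickness and caliber on the
scale of the rectum. Planted deformations displace the whole wall radially:
`inward_radial` (toward the lumen), `outward_radial`, or `mixed` (half the
circumference outward, the opposite half inward — a one-sided bulge with
luminal intrusion opposite, the variable pattern described for
poorly-responding tumors). The displacement is applied analytically, so
every ground-truth vector's norm and centroid angle are exact — an absolute
oracle for the descriptor stages. Cohorts (`make_cohort()`) add geometric
jitter (radii, centerline bow, axial extent) and a class contrast chosen
once: responders get 0.8 mm (SD 0.3) inward-only displacement — sub-voxel,
near-healthy anatomy — while non-responders get 4 mm (SD 1) mixed
displacement, i.e., structural change on the scale of the wall thickness,
with stronger intensity heterogeneity. The responder fraction defaults to
0.36, the composition of the reference cohort.

The phantoms deliberately do not emulate MRI physics (bias fields, coil
profiles), anatomically realistic wall shape, or partial-volume effects
beyond grid discretization. A green phantom test therefore establishes that
the algorithmic chain — registration, inversion, descriptor, selection,
classification — recovers planted structure at realistic scales; it cannot
establish clinical performance, which can only be measured on restricted
clinical cohorts.

## Statistical machinery

* **mRMR**: greedy mutual-information-difference ranking on
  equal-frequency tertile bins.
* **Cross-validation**: 50 runs of 3-fold stratified CV; per fold,
  standardization and selection use the training fold only (a leakage test
  asserts this); per run a bootstrapped AUC (median over 100 patient-level
  resamples of the pooled out-of-fold scores).
* **Classifiers**: LDA/QDA via MASS with class-frequency priors; the random
  forest is a compact in-package implementation (bootstrap + gini CART,
  sqrt(p) candidate features per split, 500 trees) because no forest
  package exists in the target environment.
* **Hold-out threshold**: Youden-optimal on the validation ROC, mirroring
  the published protocol; this is optimistic by construction and documented
  as such.
* **Instability score**: the published 0-1 index has no public formula; the
  surrogate is each feature's between-group rank dispersion divided by the
  maximum achievable for the observed group sizes, so 0 = unaffected by
  acquisition grouping and 1 = fully determined by it.
* **Consensus clustering**: 1000 iterations, 80% patient resampling,
  average-linkage hierarchical clustering with Pearson profile distance,
  cut at k = 2; consensus = co-cluster count over co-sample count; the
  final assignment cuts a tree of 1 - consensus. Clustering operates on the
  3-D t-SNE projection (perplexity 30, auto-reduced for small cohorts,
  1000 iterations, Euclidean metric), as in the published analysis.
* **Positive FDR**: Storey q-values (lambda grid; spline-smoothed pi0 for
  large families, the conservative `2 * mean(p > 0.5)` estimate for small
  ones), flagged at q <= 0.3. Tests cross-check the null flag rate against
  an independent Benjamini-Hochberg step-up implementation.

## Known limitations

* The registration engine is tuned for the phantom geometry and the
  organ-scale deformations of this problem; it is not a general-purpose
  replacement for ITK-class registration.
* NMI-driven deformable registration of near-symmetric synthetic structures
  is intrinsically ill-posed (see above); the structural channel is the
  supported configuration for phantom work.
* No complete public inventory exists for the 764-feature texture bank
  used in the original clinical analyses; the implemented bank covers the
  families that matter downstream (Gabor bank,
  Sobel variants, CoLlAGe Haralick set, five first-order statistics each)
  with its size recorded in the output metadata.
* Atlas construction assumes the cohort is already resampled to a common
  grid; sex-specific atlases and automated wall segmentation are out of
  scope (masks are inputs).

## Worked example

```{r example}
library(stodeo)

# a complete phantom study: atlas, registration, descriptors, texture
st <- phantom_study(n = 24, seed = 1)
feats <- setdiff(feature_columns(st$table), "wall_volume")

# supervised evaluation
rep <- run_cv(st$table, feats, "lda", n_runs = 10, n_folds = 3,
              n_select = 11, seed = 2)
print(rep)

# unsupervised evaluation
emb <- tsne_project(scale(as.matrix(st$table[, feats])), dims = 3, seed = 3)
cc <- consensus_cluster(emb, k = 2, iters = 500, seed = 4)
cluster_overlap_accuracy(cc$assignment, st$table$label)

# radiomic-biology correlation against synthetic cell counts
cells <- make_cell_counts(st$table[, c("median_mag", "std_mag")],
                          coupling = matrix(c(0.8, rep(0, 7)), 4, 2),
                          seed = 5)
head(spearman_fdr_map(st$table[, feats[1:6]], cells))
```
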