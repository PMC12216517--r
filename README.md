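# stodeo

Structural modeling magnitude and orientation (StODeO) radiomics for
hollow-organ walls.

## What this solves, and for whom

After neoadjuvant therapy for locally advanced rectal cancer, the key
clinical question is whether the tumor has regressed — radiologic staging
on T2w MRI agrees with pathology barely better than chance. This package is
for imaging researchers who want a quantitative surrogate of that
structural change: it measures, voxel by voxel, how far and in which
direction a patient's rectal wall sits relative to a canonical
*non-diseased* atlas of the organ, and turns those displacement fields into
a compact descriptor for response classification.

For an atlas `A` registered to a patient scene `I` (rigid, affine, then
cubic b-spline free-form deformation driven by normalized mutual
information), the composite transform is inverted to map `I` into atlas
space. At every wall voxel `c'` with displacement `(dx, dy, dz)`:

* magnitude `D(c') = sqrt(dx^2 + dy^2 + dz^2)` — summarized by median,
  SD, skewness and kurtosis (`F_m`, 4 values);
* orientation `theta(c') = arccos(v'. v0 / (|v'||v0|))` against the
  direction `v0` to the lumen centroid — quantized into five bins
  (0-20, 20-80, 80-100, 100-160, 160-180 degrees; bin 1 = inward
  displacement, bin 5 = outward), computed on the high-deformation region
  isolated by MRF clustering (6 classes, 8 iterations, potential 0.5)
  (`F_o`, 5 values).

Combined with a texture bank (Gabor, Sobel gradient, CoLlAGe), the features
feed mRMR selection with LDA/QDA/random-forest classifiers under 50 runs of
3-fold cross-validation, hold-out evaluation, consensus clustering of t-SNE
projections, and Spearman/positive-FDR correlation against immune-cell
counts. Because the clinical cohorts are IRB-restricted, the package ships
a hollow-tube phantom generator with *analytic* ground-truth deformation
fields, so every stage is testable without clinical data.

## Worked example

```r
library(stodeo)

# phantom study: healthy atlas, 24 deformed patients (36% "responders"),
# registration, StODeO + texture features
st <- phantom_study(n = 24, seed = 1)
aggregate(cbind(median_mag, fo_bin1, fo_bin5) ~ label, st$table, median)
#>           label median_mag   fo_bin1 fo_bin5
#> 1 non-responder   5.225035 0.0000000       0
#> 2     responder   1.595983 0.6646341       0

feats <- setdiff(feature_columns(st$table), "wall_volume")
rep <- run_cv(st$table, feats, "lda", n_runs = 10, n_folds = 3,
              n_select = 11, seed = 2)
rep$metrics["mean", "auc"]
#> [1] 0.98333
```

Responder phantoms (sub-millimeter inward displacement) show small
magnitudes with orientation mass in bin 1 (toward the lumen); non-responder
phantoms (wall-thickness-scale mixed displacement) show magnitudes around
5 mm without that inward concentration — and the cross-validated classifier
separates the groups almost perfectly at these planted effect sizes.

Single-patient use follows the same stages: `resample_volume()` /
`center_crop_to_roi()`, `build_atlas()` or `load_atlas()`,
`register_atlas_to_patient()`, `extract_displacements()`,
`compute_stodeo()` and `extract_texture_features()`. A thin command-line
wrapper with per-stage subcommands is installed at `inst/cli/stodeo.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main pipeline from scratch — atlas construction
from healthy phantoms, registration of a labeled deformed cohort,
StODeO + texture feature extraction, cross-validated classification and
consensus clustering — printing the summary measures it computes and
writing the JSON report to `--out`.

## Layout

* `R/`, `src/` — implementation (IO and preprocessing, phantom generator,
  registration engine with C++ core, descriptor, texture, ML and
  unsupervised statistics)
* `tests/testthat/` — unit, property and acceptance suites
* `vignettes/stodeo-methods.Rmd` — the methods vignette: model,
  conventions, registration design, what the phantoms do and do not
  establish
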