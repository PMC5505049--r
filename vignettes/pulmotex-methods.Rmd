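---
title: "Texture-based classification of pulmonary CT: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture-based classification of pulmonary CT: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pulmotex)
```

`pulmotex` quantifies the spatial grey-level structure of lung parenchyma on
CT and asks how well that structure discriminates healthy dogs from diseased
dogs with and without pulmonary thromboembolism (PTE). This vignette is the
package's own account of the models it implements, the parameters that
matter, and the design decisions taken where the method is underdetermined.

## The analysis model

### Segmentation and quantization

Parenchyma is isolated purely by attenuation: pixels with HU in
[−1024, −250] are retained, everything else is invalid. The upper bound
excludes poorly- and non-aerated lung, consolidation and soft tissue, so the
texture statistics describe aerated parenchyma only. Invalidity is a
type-level flag (logical mask plus `NA` values), never a sentinel number —
a 0 HU "background" pixel would otherwise contribute spurious co-occurrence
pairs.

Retained HU are binned into *G* = 64 equal-width levels. The bins span the
segmentation window itself rather than each image's min–max
(`quantize.mode = "fixed_window"`, with `"per_image"` available): per-image
scaling would erase between-image brightness differences, which are real
physiology (hypo-/hyper-attenuation) rather than acquisition artefact once
values are in HU. Bins are left-closed, right-open with a right-closed last
bin, so every in-window value maps to exactly one level and the window
ceiling maps to level *G*. 64 levels keeps the 64×64 GLCM well populated on
a few thousand parenchymal pixels per slice while retaining attenuation
detail.

### Masked co-occurrence matrices

For orientation offsets (0°, 45°, 90°, 135°) at distance 1 pixel, pairs are
counted only where **both** pixels are valid: any pair touching background,
the lung boundary, or the image border is not parenchymal texture and is
excluded. Accumulation is symmetric — each pair feeds (*i*, *j*) and
(*j*, *i*) — following Haralick's original definition; this also makes 0°
and 180° equivalent, which is why exactly four orientations suffice. The
matrix is normalized to unit mass after symmetrization. A slice whose mask
admits no pair at some orientation raises a classed condition and is dropped
(and logged) by `feature_table()`.

### The 22-feature bank

All features are computed from the normalized GLCM *p*(*i*, *j*), its
marginals, and the sum (*i*+*j*) and absolute-difference |*i*−*j*|
distributions. Conventions, fixed package-wide:

* natural logarithms, with 0·log 0 ≡ 0;
* the two correlation forms (`corrm`, `corrp`) are algebraically identical
  and both are reported; their agreement to 1e−10 is a standing regression
  test;
* for a constant region the marginal SDs vanish; the correlation features
  are returned as their defined limit 0 and the vector is flagged
  (`degenerate_sd`);
* sum variance (`svarh`) is centred on sum entropy, per Haralick's printed
  definition; the common alternative centring on sum average is available
  via `sum_variance_center = "sum_average"` because the literature is
  genuinely ambiguous here;
* features are kept per orientation (88 columns), not orientation-averaged:
  all four orientations carry signal and the classifiers can weight them.

Every feature is checked against an independent brute-force double-loop
implementation on random masked images to 1e−10 in the test suite.

### Classification

All three models operate on autoscaled columns (mean 0, SD 1, learned on
training rows only; constant columns get an SD floor of 1e−12). The 88
features span several orders of magnitude — autocorrelation is O(*G*²),
energy is ≤ 1 — so unscaled fits would be dominated by a handful of columns.

* **PCA** (via SVD) is exploratory: on the default synthetic cohort it
  separates healthy from diseased along the leading components while the two
  diseased classes overlap, which is exactly the regime the supervised
  models then quantify.
* **PLS-DA** regresses the autoscaled features on a one-vs-rest indicator
  matrix (one column per class) with NIPALS-extracted latent variables that
  maximize covariance between feature scores and the class indicators.
  Default 3 latent variables; at full rank the fit provably collapses to
  least-squares regression (tested). Hard labels are the argmax of the class
  responses — well-defined for three classes, unlike 0.5-thresholding — and
  the continuous responses feed the ROC curves.
* **SVM** uses a Gaussian kernel with one-vs-one voting (libsvm via e1071).
  Defaults are scale-free: γ = 1/88 on autoscaled data (unit column
  variance), C = 1. The per-class continuous response for ROC aggregates the
  signed pairwise decision values, which keeps prediction deterministic (no
  Platt probability calibration, which would introduce internal random
  partitions).

### Evaluation

Cross-validation is leave-one-dog-out: the slice is the statistical unit but
the dog is the exchangeable unit, so all slices of one dog form the test
fold and scaling plus model are refit on the remaining dogs. Pooled held-out
predictions give the CV metrics; a single fit on everything gives the
calibration (resubstitution) metrics. Per class (one-vs-rest):
sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), 95% Wilson score
intervals (chosen because Wilson behaves at proportions of 0 or 1, which
perfect healthy classification actually produces), and
classification error = 1 − (sensitivity+specificity)/2, the balanced error
convention of the chemometrics toolbox family. ROC curves sweep every
response threshold; AUC is trapezoidal; a constant response yields the
diagonal with AUC 0.5, flagged rather than erroring.

### Bootstrap contrast between the diseased groups

The two diseased groups are small and unequal (7 vs 22 dogs), so mean
differences in individual features are tested by bootstrap rather than
t-test. The null is the translation null: both samples are shifted to the
pooled mean and resampled with replacement within group at original sizes.
The test statistic is the **studentized** mean difference
(mean(a)−mean(b))/√(s²_a/n_a + s²_b/n_b). With the raw difference the
translation bootstrap is markedly anti-conservative at these sizes (the
within-group empirical variances underestimate sampling variance at n = 7);
studentizing restores the nominal level, and the package's calibration test
(type-I error within Monte-Carlo bounds of α = 0.05 at n = 7 vs 22) holds
only in this form. Reported `observed_diff` stays the plain mean difference.
Two-sided p = (1 + #{|T*| ≥ |T|})/(B+1); the +1 smoothing forbids p = 0 at
finite B. The default screen tests six features (entropy, energy,
correlation, homogeneity, sum variance, inverse difference normalized) in
the horizontal orientation, per-feature without multiplicity correction (a
Bonferroni flag is available); `homom` vs `homop` and `corrm` vs `corrp`
are deliberate defaults where the plain names "homogeneity" and
"correlation" are ambiguous.

## The synthetic study generator

Real CTPA scans for this problem are not publicly available, so the
generator is a first-class, tested module that emulates the statistical
structure the analysis assumes:

* **Cohort:** 6 healthy, 7 PTE, 22 non-PTE dogs, 20 slices per dog by
  default. The number of slices per dog entering such analyses is typically
  not fixed by protocol; 20 gives several hundred slices total — enough for
  stable pooled metrics — while keeping a full run in tens of seconds.
* **Geometry:** two axis-aligned elliptical lung fields in a +40 HU
  soft-tissue background. This is deliberately minimal: it produces a
  non-trivial mask with background both outside and *between* the lungs,
  which exercises the masked-GLCM pair exclusion, and the +40 HU background
  is removed by the standard window exactly as soft tissue is in real scans.
* **Texture:** white Gaussian noise smoothed by a Gaussian kernel of scale
  `correlation_length` (circular convolution keeps the field stationary),
  standardized and rescaled to (`mean_hu`, `sd_hu`), plus a Poisson number
  of Gaussian-profile hyperdense blobs. The two knobs map directly onto the
  feature bank: correlation length drives contrast/homogeneity (and the
  suite verifies contrast falls monotonically as correlation length rises),
  blobs perturb the grey-level distribution tails.
* **Class structure:** healthy parenchyma is smoother (correlation length
  3.5 px vs 1.2), darker (−780 vs ≈ −700 HU) and less variable (SD 70 vs
  95 HU) than diseased; the two diseased classes share field statistics and
  differ only in blob rate and contrast (3 vs 1.5 expected blobs, 120 vs
  110 HU). Values are chosen so mean ± 3 SD stays inside the segmentation
  window (designs violating this are rejected as unusable) and so that the
  healthy class is clearly separable while the diseased classes overlap
  strongly — the qualitative regime the pipeline is meant to reproduce.
* **Between-dog variability:** each dog perturbs its class parameters by a
  Gaussian random effect with SD = `dog_sigma` (default 0.1) times the
  between-class spread of that parameter. This makes leave-one-dog-out CV
  strictly harder than pooled CV, as it is with real subjects.
* **Determinism:** a single seeded RNG stream; identical seeds give
  bit-identical pixel arrays, and the end-to-end pipeline writes
  byte-identical CSVs under a fixed seed.

What the generator does **not** emulate: anatomy (vessels, airways, lobes,
actual clots), CT reconstruction physics, slice-to-slice anatomical
continuity within a dog, motion, or scanner-dependent noise spectra.
Consequently, passing tests demonstrate that the pipeline's statistics,
masking, cross-validation and inference behave correctly under a controlled
texture model with the study's cohort structure — not that the specific
sensitivities measured here transfer to clinical scans.

## Numerical choices and degenerate inputs

* HU range accepted after rescale: [−1024, 3071]; 16-bit TIFF storage is
  offset-encoded (stored = HU + 1024) with the offset declared, keeping
  negative HU representable in unsigned format; round-trips are tested to
  1 HU.
* DICOM reading converts stored values via the file's rescale slope and
  intercept; files missing those tags fall back to slope 1 / intercept 0
  with a warning. Only single-frame explicit-VR little-endian CT files are
  supported, which covers the transverse-slice exports this analysis
  consumes.
* Empty segmentation masks and pair-free GLCMs are classed conditions;
  `feature_table()` drops such slices, reports them, and the run log
  reconciles input = used + excluded.
* PLS-DA NIPALS iterates to a relative tolerance of 1e−12 (cap 500
  iterations) per latent variable; component signs are data-dependent but
  all reported quantities are sign-invariant.
* Ties in the argmax class assignment are broken by class order and
  reported via a message.
* CV folds whose training set loses an entire class are skipped with a
  warning and the report annotates the skipped dogs; metrics that would
  divide by zero (a class absent from the pooled predictions) are returned
  as flagged `NA`, never silently 0.

## Problem sizes used by the tests

The suite runs the full default cohort (35 dogs × 20 slices of 128×128
pixels) across five seeds for the pattern-recovery checks, 64×64-pixel
variants of the same cohort for structural checks, 100 random masked images
(≤ 16×16, G ≤ 8) for oracle equivalence, and 1000 replicates × 2000
resamples for bootstrap calibration. These sizes give stable Monte-Carlo
bounds (3σ bands are asserted wherever a rate is checked) while a complete
run of suite plus acceptance script stays in the minutes range on one CPU.

## Known limitations

* The generator's texture model is stationary within the lung field; real
  parenchyma has gravity-dependent gradients and structured anatomy, so
  absolute feature values here are not clinically interpretable.
* Classification error is reported as the balanced per-class error; other
  conventions (overall misclassification rate, per-dog majority voting)
  would give different numbers and are not implemented.
* Confidence intervals are computed over slices, which are correlated
  within dog; they understate dog-level uncertainty. The CV structure (not
  the CIs) is what guards against within-dog leakage.
* No inner hyperparameter search is performed by default (3 latent
  variables, γ = 1/p, C = 1); the defaults are scale-free and each learner
  specification accepts overrides.
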