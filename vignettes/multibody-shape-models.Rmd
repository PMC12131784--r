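---
title: "Multi-body statistical shape models: methods and design notes"
author: "mbssm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-body statistical shape models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbssm)
```

## The model

A point-distribution shape model describes a population of corresponded 3D
point clouds — clouds in which the *i*-th point marks the same anatomical
location on every subject — by a mean shape and a small set of orthonormal
deformation directions. Each cloud of *m* points is flattened into a
3*m*-vector `[x1, y1, z1, ..., xm, ym, zm]` (mm throughout); for a paired
structure such as the shoulder's scapula and proximal humerus, the two
bodies' vectors are concatenated into one combined vector whose block layout
is retained. PCA of the *n* training vectors (thin SVD of the centred data
matrix; sample-covariance `1/(n-1)` convention) yields eigenvectors `phi_i`
and eigenvalues `lambda_i`, and new shapes are

```
y = mean + Phi %*% b,      b_i ~ N(0, lambda_i)  (independent)
```

Key modelling assumptions, inherited from the point-distribution-model
tradition:

* **Pose is removed before modelling.** Every body is centred at its
  centroid (a pure translation), so PCA captures shape, not position.
  `shape_model()` checks the centring rather than silently applying it.
  Rotational alignment is assumed done upstream (correspondence tools
  align during grooming); the package performs no Procrustes step.
* **No size normalisation.** The data are not rescaled, so overall size
  variation stays in the model — size is anatomy here, not nuisance.
* **Gaussian, low-rank variation.** *n* training samples support at most
  *n − 1* non-trivial modes (the mean absorbs one degree of freedom);
  eigenvalues below `1e-10 * lambda_1` are discarded as numerical zeros.
  Eigenvector signs are fixed (largest-magnitude entry positive) so fits
  and reports are reproducible across platforms.

Fitting a target `x` uses `b = t(Phi) %*% (x - mean)` (the transpose is the
pseudo-inverse of an orthonormal-column matrix), then a two-step
plausibility filter: clip each coefficient to `±3 sqrt(lambda_i)`, then
scale uniformly by the factor closest to 1 such that
`sum((s b_i)^2 / lambda_i) <= qchisq(0.997, n - 1)`. Minimising `(s - 1)^2`
under a single quadratic constraint has the closed form
`s = min(1, sqrt(qchisq(0.997, n-1) / Q))`; a generic constrained optimiser
is kept only as a test oracle. Defaults (clip multiple 3, level 0.997,
df = n − 1) are the field's conventional plausibility ellipsoid and are
arguments everywhere they matter.

## Distances and validation battery

Errors are reported as the **average Euclidean point distance** `d` (mean
over corresponding points; directly interpretable in mm), the **RMS**
difference over all 3*m* coordinates, and the **bidirectional Hausdorff
distance** (worst-case nearest-neighbour discrepancy, correspondence-free).
By Jensen's inequality `d <= sqrt(3) * RMS`, and the mean per-point distance
never exceeds the RMS of per-point distances; the test suite asserts these
provable forms rather than the loose folklore `d > RMS`. Hausdorff distances
are computed by exact blockwise brute force at every size (the candidate
nearest neighbour is located with the Gram expansion, then its distance is
recomputed by direct subtraction so cancellation error cannot reach the
result).

The validation battery is the standard quartet:

* `loo_ground_truth()` — leave-one-out: rebuild on *n − 1*, fit the left-out
  shape with all *(n−1)−1* modes, regularise, measure `d` and Hausdorff, and
  also record the distance from the training mean (how much of the accuracy
  the mean alone provides).
* `generalization_by_samples()` — the same, with the training set
  subsampled to *k* subjects (one random subset per (k, fold); a single
  master seed derives per-(procedure, k, fold) child streams, so reports are
  reproducible and, at *k = n − 1*, reduce to the leave-one-out record for
  record).
* `generalization_by_components()` — full LOO with the fit truncated to the
  leading *k* modes; equals LOO at *k = n − 2*.
* `specificity_test()` — distance from model-sampled shapes to their
  closest training member, per number of modes; the full study-scale default is
  M = 10,000 draws, reducible for quick runs.

## Two-body coupling

For a combined model, each eigenvector splits by the block layout into a
scapula part `phi_CS_j` and a humerus part `phi_CH_j`, with
`||phi_CS_j||^2 + ||phi_CH_j||^2 = 1`. Because the combined and single-body
models are trained on the same centred data, each block lies in the span of
that body's own eigenvectors, and the weights
`gamma_j = t(Phi_S) %*% phi_CS_j` decompose combined modes into single-body
modes with vanishing residual. Normalised absolute weights form the
contribution heatmap `A`.

Two variance attributions are reported, and the distinction matters:

* **Weight-based** (`variance_attribution()`):
  `v_j = sum_i gamma_j[i]^2 * share_i` with `share_i` the single-body
  eigenvalue shares. Its rows are bounded (`sum_j v_j <= 1`), but the
  sub-unit block norm enters squared twice, so even a perfectly coupled
  pair tops out near 0.5 cumulatively — useful as a weight diagnostic, not
  as variance bookkeeping.
* **Exact** (used by `coupling_report()`):
  `v_j = lambda_C[j] * ||phi_block_j||^2 / V_body`. Because empirical
  combined scores are exactly uncorrelated, this decomposes each body's
  total training variance exactly: `sum_j v_j = 1` per body.

The per-mode **coupled variation** is `v_J[j] = min(v_scapula[j],
v_humerus[j])` — variation of the two bodies that co-occurs along one
combined mode — and its cumulative sum is the total coupled variation. On
synthetic cohorts with known coupling fraction *f* the exact attribution
recovers *f* to three decimals across the whole grid `f = 0, ..., 1`; the
weight-based form saturates near 0.43 at *f = 1*, which is why the exact
form drives the report.

`contribution_covariance()` exposes the block decomposition of combined
coefficients, `b = b_S + b_H`, and their cross-covariance both empirically
and via the closed form `t(Phi_CS) %*% Sigma_SH %*% Phi_CH` (they agree
algebraically; the test asserts 1e-8 relative agreement).

## Missing-counterpart prediction

`predict_counterpart_loo()` predicts one body from its partner: per fold,
a random-forest regressor (200 trees by default, one forest per output
coordinate, per-fold deterministic seeds) maps the given body's
contribution vector `b_1` to the target's `b_2`, the prediction is
plausibility-filtered, and the target is reconstructed as
`mean_2 + Phi_C2 %*% b_hat_2`. The baseline — all an independent
single-body model can offer — is the training mean, since
`E(x_2 | x_1) = mean(x_2)` without modelled coupling.

One design point was forced by the algebra. Block contributions are **not**
distributed `N(0, lambda_C)`: along near-null combined modes the two
bodies' contributions are individually large and cancel, so each block's
own variance far exceeds the combined eigenvalue. A filter that clips and
scales `b_hat_2` against `lambda_C` therefore rejects even the *true*
contribution vector (measured Mahalanobis sums of order 1e4 against a
chi-squared bound of ~73) and crushes informative modes; the filter here
uses per-mode variances estimated from the training contributions — the
correct Gaussian ellipsoid for that vector — with the same 3-sd clip and
`qchisq(0.997, n-1)` form. Note also that the block reconstruction itself
shrinks: `Phi_C2 %*% b_2` recovers only the part of the target deformation
weighted by the block norms, so even oracle coefficients do not reach zero
error; this is inherent to predicting through a combined model's blocks.

## De novo population generation and bias

The **plausibility** of a shape is `1 - pchisq(Q, n - 1)` with `Q` its
Mahalanobis sum. Shapes genuinely sampled from the model have uniformly
distributed plausibilities (probability integral transform), so a
generation scheme is unbiased exactly when its plausibility sample passes a
one-sample Kolmogorov–Smirnov test against Uniform(0, 1).
`generate_combined()` samples the combined model directly and is unbiased
by construction. `generate_independent()` samples each body from its own
single-body model, ignoring any coupling; on coupled cohorts its
plausibilities collapse toward 0 (mismatched pairs) and the KS test rejects
decisively — the bias that motivates combined modelling.

Conventions and caveats:

* The KS test reported is the standard one: a *small* p-value rejects
  uniformity. (Descriptions that read a small p-value as *supporting*
  uniformity invert this convention and are not reproduced.)
* The chi-squared df defaults to `n - 1`, which matches the uniformity
  construction only when the model carries all `n - 1` modes — true for
  any cohort with non-zero measurement noise. For deliberately reduced-rank
  (noise-free) models, pass `df = <retained modes>`.
* Exact distributional equivalence of the two schemes on *uncoupled*
  cohorts holds only in the well-separated-spectrum regime: with a noisy
  full-rank spectrum, the combined PCA's near-degenerate noise eigenvectors
  align with spurious empirical cross-covariance between the bodies, so the
  independent scheme drifts from uniformity even at zero true coupling.
  The package reports the per-draw out-of-span residual as a diagnostic.
* Independent-scheme combined coefficients are fitted *unregularised* —
  plausibility must be free to fall outside the ellipsoid to measure bias.

## The synthetic cohort generator

`generate_cohort()` realises a ground-truth latent model standing in for a
clinical CT-derived cohort: two templates at anatomical scale (~150 mm
curved plate for the scapula, cylinder-with-hemispherical-head for the
proximal humerus), deformed by smooth orthonormal fields — a uniform
scaling field, a localised inward "erosion" dent at the articular analog
(so the coupled glenoid/humeral-head erosion phenomenon has a synthetic
counterpart), and broad random Gaussian bumps — driven by latent scores
that are partly shared between the bodies. The coupling fraction *f*
allocates each body's deformation variance between shared and
body-specific latents exactly, so `ground_truth_coupling()` is exact by
construction, not estimated.

Defaults (chosen once as a realistic reduced-scale shoulder cohort): 45
subjects; 160 and 154 points per body (full-resolution 1600/1536 available via
`m_per_body`); 4 shared + 4 own latents per body with a geometric variance
spectrum (ratio 0.55); total deformation variance 1000 and 640 mm²
(per-point RMS deformation ≈ 2.5 and 2 mm); 0.1 mm i.i.d. correspondence
jitter. Latent scores are empirically standardised (centred,
orthogonalised, exact unit sample variance), so a noise-free cohort's
sample spectrum equals the constructed one *exactly*; i.i.d. scores would
carry ~20% sampling noise per eigenvalue at n = 45, which would make
spectrum-recovery checks meaningless at this scale. When the latent count
reaches `n`, exact orthogonalisation is impossible; the generator warns and
falls back to centred unit-variance scores.

What the generator does **not** emulate: anatomically realistic surfaces,
correspondence error structure (jitter is i.i.d., real correspondence error
is spatially correlated), outlier anatomies, left/right chirality, or
non-Gaussian pathology clusters. Passing tests on these cohorts
demonstrates the algebra and the statistical machinery, not clinical-level
accuracy; the headline clinical error magnitudes of any real cohort are not
reproducible from synthetic data.

## Problem sizes and numerical choices

The test suite and the acceptance script run cohorts of n = 45 subjects at
40–60 points per body — small enough for seconds-scale model builds while
keeping the full n − 1 = 44-mode structure of the study design — and
M = 2000 draws for distributional tests (the package defaults remain at
the full study scale, M = 10,000). Degenerate inputs are errors, not warnings:
uncentred training data, zero-variance cohorts in cross-validation,
mismatched vector lengths, chi-squared df ≤ 0, coefficient vectors longer
than the retained rank. Ties in nearest-neighbour searches break toward
the first index; all RNG flows through explicit seeds with deterministic
child-stream derivation.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_cohort_spec(n_subjects = 45, coupling_fraction = 0.5,
                              seed = 17)
cohort <- generate_cohort(spec)
combined <- shape_model(cohort)
summary(combined)

loo <- loo_ground_truth(cohort)
summary(loo)

rep <- coupling_report(cohort)
rep                      # per-mode and cumulative coupled variation

pop <- generate_combined(combined, M = 10000, seed = 18)
pop                      # KS uniformity of plausibilities
```
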