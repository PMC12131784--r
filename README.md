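# mbssm — multi-body statistical shape models

Statistical shape models (point-distribution models) learn a population's
anatomy from corresponded 3D point clouds: a mean shape plus orthonormal
modes of variation with variances, obtained by PCA over the flattened
coordinate vectors. `mbssm` builds such models for a single body **or for
several bodies jointly** — the motivating case being the scapula and
proximal humerus of the shoulder, whose shapes co-vary in disease — and
provides everything around them:

* model construction (`shape_model()`), fitting with Mahalanobis
  plausibility regularization (`predict()`, `regularize_params()`),
  sampling (`simulate()`), compactness and mode sweeps;
* the standard validation battery: leave-one-out ground-truth accuracy,
  generalization by training-set size and by number of components,
  specificity — all reporting average Euclidean point distance and
  bidirectional Hausdorff distance in mm;
* quantification of **coupled two-body variation**: each combined-model
  eigenvector is split by body and decomposed into single-body modes;
  the per-mode coupled variation is `v_J[j] = min(v_scapula[j],
  v_humerus[j])`, the variance both bodies express along the same combined
  mode;
* **missing-counterpart prediction**: a random-forest regressor on
  block-decomposed model coefficients predicts one body's shape from its
  partner, evaluated leave-one-out against the training-mean baseline;
* **de novo population generation** with bias assessment: shape
  plausibility `1 - pchisq(Q, n-1)` is uniform for unbiased generators, so
  a Kolmogorov–Smirnov test against Uniform(0,1) detects the bias of
  sampling two coupled bodies independently;
* a seeded **synthetic paired-cohort generator** with an exact,
  controllable coupled-variance fraction, used as ground truth throughout
  the test suite.

The model, in the field's standard notation: shapes are vectors
`x = [x1,y1,z1,...,xm,ym,zm]` (mm, centred per body); PCA of the training
matrix gives `Phi = [phi_1 ... phi_{n-1}]` and eigenvalues
`lambda_1 >= ... >= lambda_{n-1}`; new shapes are `y = mean + Phi b` with
`b_i ~ N(0, lambda_i)`, constrained to the plausibility ellipsoid
`sum(b_i^2 / lambda_i) <= qchisq(0.997, n-1)` by per-mode clipping at
`3 sqrt(lambda_i)` followed by closed-form uniform scaling. For two bodies
the combined vector is the concatenation (1600-point scapula + 1536-point
humerus → 9408 elements at full resolution) and every eigenvector carries a
scapula block and a humerus block whose squared norms sum to 1.

## A worked example

```r
library(mbssm)

spec    <- synthetic_cohort_spec(n_subjects = 45, coupling_fraction = 0.5,
                                 seed = 17)
cohort  <- generate_cohort(spec)        # 45 paired scapula/humerus clouds
combined <- shape_model(cohort)         # two-body model
combined
#> Statistical shape model (scapula + humerus)
#>   training shapes : 45
#>   points          : scapula=160, humerus=154
#>   modes retained  : 44
#>   leading eigenvalues (mm^2): 406.5, 247.7, 223.9, 158.7, 136.5

loo <- loo_ground_truth(cohort)
median(loo$d_avg); median(loo$baseline_d_avg)
#> 0.182 mm vs 1.955 mm for the training-mean baseline

coupling_report(cohort)
#> Coupled-variation report: scapula + humerus, 44 combined modes
#>   total coupled variation: 50.1% of per-body variance
#>  mode v_scapula v_humerus v_joint
#>     1    0.2466    0.2461  0.2461
#>     2    0.2463    0.0002  0.0002
#>     3    0.1361    0.1352  0.1352
#>     4    0.0001    0.2461  0.0001
#>     5    0.1356    0.0002  0.0002
#>     6    0.0750    0.0747  0.0747

generate_combined(combined, M = 10000, seed = 18)
#> De novo population: scheme 'combined', M = 10000 shapes
#>   plausibility quartiles: 0.248 / 0.506 / 0.751
#>   KS uniformity: D = 0.0063, p = 0.824
```

Read it as follows. The leave-one-out median of 0.18 mm against a 1.96 mm
baseline says the 44 modes describe held-out anatomy an order of magnitude
better than the mean shape alone. The coupling report recovers the
generator's ground truth: the cohort was built with half of each body's
variance on shared latents, and the cumulative coupled variation comes out
at 50.1% — modes 1, 3 and 6 are shared (both bodies express them), modes 2,
4 and 5 are body-specific (one body's share is ~0). The KS p of 0.82
confirms that sampling the combined model produces an unbiased population;
rerunning `generate_independent()` on a coupled cohort instead drives the
KS p below 1e-3, the bias that makes the two-body model necessary for
generative use.

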