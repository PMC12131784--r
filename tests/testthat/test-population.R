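co <- generate_cohort(small_spec(n = 20, seed = 51, noise = 0.05))
combined <- shape_model(co)

test_that("plausibility is 1 at the mean, 0.5 at the chi-squared median, and decreasing", {
  r <- mbssm:::n_modes(combined)
  expect_equal(plausibility(combined, rep(0, r)), 1)
  df <- combined$n_train - 1L
  b_med <- c(sqrt(combined$eigenvalues[1] * qchisq(0.5, df)), rep(0, r - 1))
  expect_equal(plausibility(combined, b_med), 0.5, tolerance = 1e-12)
  # strictly decreasing in the Mahalanobis sum
  qs <- seq(0.5, 60, length.out = 30)
  ps <- vapply(qs, function(q)
    plausibility(combined, c(sqrt(combined$eigenvalues[1] * q),
                             rep(0, r - 1))), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(plausibility(combined, rep(0, r), df = 0), "degrees of freedom")
})

test_that("KS uniformity statistic matches direct computation", {
  u <- (1:200) / 201
  ks <- ks_uniformity(u)
  expect_lt(ks$statistic, 0.01)
  expect_gt(ks$p_value, 0.99)
  point_mass <- rep(0.9, 50)
  ks2 <- ks_uniformity(point_mass)
  expect_equal(ks2$statistic, 0.9, tolerance = 1e-9)
  expect_lt(ks2$p_value, 1e-10)
  expect_error(ks_uniformity(runif(5)), "at least 8")
  expect_error(ks_uniformity(c(runif(10), 1.2)), "0, 1")
})

test_that("combined-scheme plausibilities are uniform (probability integral transform)", {
  pop <- generate_combined(combined, M = 2000, seed = 61)
  expect_true(all(pop$plausibilities >= 0 & pop$plausibilities <= 1))
  expect_gt(pop$ks_p, 0.01)
  expect_equal(pop$quartiles, c(0.25, 0.5, 0.75), tolerance = 0.05)
  # deterministic under seed
  pop2 <- generate_combined(combined, M = 2000, seed = 61)
  expect_identical(pop$plausibilities, pop2$plausibilities)
  expect_error(generate_combined(combined, M = 0), "M must")
})

test_that("independent-scheme sampling is unbiased for truly independent bodies", {
  # valid regime for the equivalence: noise-free, well-separated spectrum,
  # plausibility df matched to the retained rank
  co0 <- generate_cohort(small_spec(n = 20, f = 0, noise = 0, seed = 52))
  cm <- shape_model(co0)
  sm <- lapply(names(co0$bodies), function(b) shape_model(co0, b))
  names(sm) <- names(co0$bodies)
  pop <- generate_independent(sm, cm, M = 2000, seed = 62,
                              df = mbssm:::n_modes(cm))
  expect_gt(pop$ks_p, 0.01)
  expect_lt(max(pop$residual_norms), 1e-6)  # block-diagonal: pairs stay in span
})

test_that("independent-scheme sampling is biased on a coupled cohort", {
  co75 <- generate_cohort(small_spec(n = 20, f = 0.75, noise = 0.05, seed = 53))
  cm <- shape_model(co75)
  sm <- lapply(names(co75$bodies), function(b) shape_model(co75, b))
  names(sm) <- names(co75$bodies)
  pop <- generate_independent(sm, cm, M = 2000, seed = 63)
  expect_lt(pop$ks_p, 0.001)
  # same models, combined scheme: no bias
  expect_gt(generate_combined(cm, M = 2000, seed = 63)$ks_p, 0.01)
})

test_that("model provenance is checked before independent generation", {
  other <- generate_cohort(small_spec(n = 20, seed = 99, noise = 0.05))
  sm_wrong <- lapply(names(other$bodies), function(b) shape_model(other, b))
  names(sm_wrong) <- names(other$bodies)
  expect_error(generate_independent(sm_wrong, combined, M = 10, seed = 1),
               "same cohort")
})
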