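co <- generate_cohort(small_spec(n = 16, f = 0.5, noise = 0.02, seed = 31))
combined <- shape_model(co)
singles <- lapply(names(co$bodies), function(b) shape_model(co, b))
names(singles) <- names(co$bodies)

test_that("block split is lossless and block norms partition each mode", {
  blocks <- split_blocks(combined)
  expect_named(blocks, c("plate", "stem"))
  restacked <- do.call(rbind, lapply(blocks, `[[`, "components"))
  expect_identical(unname(restacked), unname(combined$components))
  expect_equal(c(do.call(c, lapply(blocks, `[[`, "mean"))), combined$mean,
               ignore_attr = TRUE)
  norm2 <- Reduce(`+`, lapply(blocks, function(b) colSums(b$components^2)))
  expect_lt(max(abs(norm2 - 1)), 1e-9)
  # a single-body model splits into one block equal to itself
  solo <- split_blocks(singles$plate)
  expect_length(solo, 1L)
  expect_identical(solo[[1]]$components, singles$plate$components)
})

test_that("combined eigenvectors decompose into single-body modes with no residual", {
  for (b in names(singles)) {
    dec <- decompose_combined_eigenvectors(combined, singles[[b]], b)
    expect_lt(max(dec$residuals), 1e-8)
    expect_equal(unname(rowSums(dec$A)), rep(1, ncol(dec$gamma)),
                 tolerance = 1e-9)
    expect_true(all(dec$A >= 0))
  }
  expect_error(decompose_combined_eigenvectors(combined, singles$plate, "nope"),
               "not in combined")
})

test_that("independent bodies give one-hot decompositions of combined modes", {
  # noise-free f=0: combined covariance is exactly block-diagonal, so each
  # combined mode is a zero-padded single-body mode
  co0 <- generate_cohort(small_spec(n = 16, f = 0, noise = 0, seed = 32))
  cm <- shape_model(co0)
  for (b in names(co0$bodies)) {
    sm <- shape_model(co0, b)
    dec <- decompose_combined_eigenvectors(cm, sm, b)
    dominant <- which(dec$block_norm2 > 0.5)   # modes living in this body
    expect_true(all(apply(dec$A[dominant, , drop = FALSE], 1, max) > 0.99))
  }
})

test_that("weight-based variance attribution follows the stated formula and bound", {
  gamma <- cbind(c(1, 0, 0))        # single combined mode = first single mode
  expect_equal(variance_attribution(gamma, c(0.5, 0.3, 0.2)), 0.5)
  expect_error(variance_attribution(gamma, c(-0.1, 0.9, 0.2)), "non-negative")
  expect_error(variance_attribution(gamma, c(0.5, 0.3)), "sum to 1")
  with_test_seed(41, {
    for (i in 1:20) {
      G <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:4]  # orthonormal columns
      sh <- runif(6); sh <- sh / sum(sh)
      v <- variance_attribution(G, sh)
      expect_true(all(v >= 0 & v <= 1))
      expect_lte(sum(v), 1 + 1e-9)
    }
  })
})

test_that("coupled variation is the per-mode minimum with monotone cumulative sum", {
  cv <- coupled_variation(c(0.3, 0.1), c(0.2, 0.4))
  expect_equal(cv$v_joint, c(0.2, 0.1))
  expect_equal(cv$cumulative, c(0.2, 0.3))
  expect_error(coupled_variation(1:3, 1:2), "length")
})

test_that("contribution covariance matches its closed form and normalizes A_B", {
  cc <- contribution_covariance(co, combined)
  rel <- max(abs(cc$cov_empirical - cc$cov_closed_form)) /
    max(abs(cc$cov_empirical))
  expect_lt(rel, 1e-8)
  expect_equal(max(cc$A_B), 1)
  expect_true(all(cc$A_B >= 0 & cc$A_B <= 1))
  # contributions sum to the full combined coefficients
  B <- Reduce(`+`, cc$contributions)
  X <- mbssm:::cohort_matrix(co)$X
  Bfull <- crossprod(combined$components, X - combined$mean)
  expect_lt(max(abs(B - Bfull)), 1e-8)
})

test_that("independent bodies show no cross-contribution covariance", {
  co0 <- generate_cohort(small_spec(n = 16, f = 0, noise = 0.02, seed = 33))
  cm <- shape_model(co0)
  cc <- contribution_covariance(co0, cm)
  scale <- sqrt(sum(shape_model(co0, "plate")$eigenvalues) *
                sum(shape_model(co0, "stem")$eigenvalues))
  expect_lt(max(abs(cc$cov_empirical)) / scale, 0.05)
})

test_that("the coupling report recovers the generator's coupled fraction", {
  rep <- coupling_report(co)
  # exact attribution sums to 1 per body
  for (b in names(co$bodies))
    expect_equal(sum(rep$v_body[[b]]), 1, tolerance = 1e-9)
  expect_true(all(rep$v_joint <= rep$v_body[[1]] + 1e-12))
  expect_true(all(rep$v_joint <= rep$v_body[[2]] + 1e-12))
  expect_true(all(diff(rep$v_joint_cumulative) >= 0))
  total <- rep$v_joint_cumulative[length(rep$v_joint_cumulative)]
  expect_equal(total, 0.5, tolerance = 0.05)   # generator f = 0.5
})

test_that("counterpart prediction validates its inputs", {
  expect_error(predict_counterpart_loo(co, "plate", "plate"), "differ")
  expect_error(predict_counterpart_loo(co, "plate", "skull"), "unknown")
})

test_that("counterpart prediction learns a deterministic coupling", {
  co1 <- generate_cohort(small_spec(n = 14, m = c(plate = 20, stem = 18),
                                    f = 1, noise = 0.02, seed = 35))
  out <- predict_counterpart_loo(co1, "stem", "plate", ntree = 100, seed = 2)
  rep <- out$report
  expect_equal(nrow(rep), 14L)
  expect_lt(median(rep$d_avg), median(rep$baseline_d_avg))
  expect_length(out$predictions[[1]]$prediction, 3L * 20L)
})
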