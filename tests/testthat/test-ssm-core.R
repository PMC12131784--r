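test_that("model construction matches a brute-force eigendecomposition", {
  X <- rand_centered_matrix(m = 30, n = 12, seed = 5)   # 3m = 90 <= 600
  mod <- shape_model(X)
  expect_equal(n_modes(mod), 11L)
  # oracle: dense sample covariance eigendecomposition
  oracle <- eigen(stats::cov(t(X)), symmetric = TRUE)
  expect_equal(mod$eigenvalues, oracle$values[1:11], tolerance = 1e-8)
  # eigenvectors agree up to sign
  dots <- abs(colSums(mod$components * oracle$vectors[, 1:11]))
  expect_true(all(dots > 1 - 1e-8))
  # orthonormality
  G <- crossprod(mod$components)
  expect_lt(max(abs(G - diag(11))), 1e-8)
  # eigenvalues sorted non-increasing
  expect_true(all(diff(mod$eigenvalues) <= 1e-12))
})

test_that("mode count follows the training-set degrees of freedom", {
  X2 <- rand_centered_matrix(m = 10, n = 2, seed = 1)
  expect_equal(n_modes(shape_model(X2)), 1L)
  same <- rand_centered_matrix(m = 10, n = 1, seed = 2)
  Xid <- same[, c(1, 1, 1, 1)]
  expect_equal(n_modes(shape_model(Xid)), 0L)
})

test_that("uncentered or undersized input is rejected", {
  X <- rand_centered_matrix(m = 10, n = 4, seed = 3)
  X[1, ] <- X[1, ] + 5   # shift every subject's x centroid
  expect_error(shape_model(X), "not centred")
  expect_error(shape_model(rand_centered_matrix(10, 4, 1)[, 1, drop = FALSE]),
               "at least 2")
})

test_that("projection recovers coefficients and reconstructs exactly in-span", {
  X <- rand_centered_matrix(m = 20, n = 10, seed = 8)
  mod <- shape_model(X)
  expect_equal(fit_params(mod, mod$mean)$b, rep(0, n_modes(mod)))
  b1 <- 2 * sqrt(mod$eigenvalues[1])
  x <- mod$mean + mod$components[, 1] * b1
  fp <- fit_params(mod, x)
  expect_lt(max(abs(fp$b - c(b1, rep(0, n_modes(mod) - 1)))), 1e-10)
  # every training member is recovered exactly with all modes
  for (j in seq_len(ncol(X))) {
    fit <- predict(mod, X[, j], regularize = FALSE)
    expect_lt(avg_point_distance(fit$reconstruction, X[, j]), 1e-8)
    expect_lt(fit$residual_norm, 1e-6)
  }
  expect_error(fit_params(mod, rnorm(10)), "length")
})

test_that("sampled shapes are refit to their sampling coefficients", {
  X <- rand_centered_matrix(m = 15, n = 8, seed = 13)
  mod <- shape_model(X)
  s <- sample_shape(mod, nsim = 5, seed = 99)
  for (j in 1:5) {
    b <- fit_params(mod, s$shapes[, j])$b
    expect_lt(max(abs(b - s$coefficients[, j])), 1e-8)
  }
})

test_that("regularization clips per-mode then scales into the chi-squared ellipsoid", {
  X <- rand_centered_matrix(m = 30, n = 45, seed = 21)
  mod <- shape_model(X)
  r <- n_modes(mod)
  expect_equal(r, 44L)
  df <- mod$n_train - 1L

  z <- regularize_params(mod, rep(0, r))
  expect_equal(z$scale_s, 1)
  expect_equal(z$b_hat, rep(0, r))
  expect_equal(z$plausibility, 1)

  # one coefficient at 5 sd: clipped to 3 sd, Q = 9 far inside the bound
  b <- rep(0, r); b[1] <- 5 * sqrt(mod$eigenvalues[1])
  f <- regularize_params(mod, b)
  expect_equal(f$b_hat[1], 3 * sqrt(mod$eigenvalues[1]))
  expect_equal(f$scale_s, 1)
  expect_equal(f$mahalanobis_q, 9)
  expect_lt(9, qchisq(0.997, df))

  # all coefficients at 3 sd: Q = 9r > bound, closed-form scale applies
  b_all <- 3 * sqrt(mod$eigenvalues)
  f2 <- regularize_params(mod, b_all)
  expect_equal(f2$scale_s, sqrt(qchisq(0.997, df) / (9 * r)), tolerance = 1e-12)
  expect_lte(f2$mahalanobis_q, qchisq(0.997, df) + 1e-6)
  # regularized coefficients always satisfy both constraints
  expect_true(all(abs(f2$b_hat) <= 3 * sqrt(mod$eigenvalues) + 1e-9))
})

test_that("closed-form scale agrees with a numeric constrained optimizer", {
  X <- rand_centered_matrix(m = 12, n = 9, seed = 31)
  mod <- shape_model(X)
  lambda <- mod$eigenvalues
  df <- mod$n_train - 1L
  qmax <- qchisq(0.997, df)
  with_test_seed(17, {
    for (i in 1:25) {
      b <- rnorm(length(lambda), sd = runif(1, 0.5, 6) * sqrt(lambda))
      fit <- regularize_params(mod, b)
      bc <- pmin(pmax(b, -3 * sqrt(lambda)), 3 * sqrt(lambda))
      Q <- sum(bc^2 / lambda)
      upper <- if (Q > 0) min(1.5, sqrt(qmax / Q)) else 1.5
      s_opt <- optimize(function(s) (s - 1)^2, c(0, upper), tol = 1e-10)$minimum
      expect_lt(abs(fit$scale_s - s_opt), 1e-6)
    }
  })
})

test_that("reconstruction is the mean plus the weighted modes", {
  X <- rand_centered_matrix(m = 10, n = 6, seed = 41)
  mod <- shape_model(X)
  expect_equal(reconstruct(mod, numeric(0)), mod$mean)
  x <- mod$mean + mod$components[, 1]
  expect_lt(max(abs(reconstruct(mod, fit_params(mod, x)$b) - x)), 1e-10)
  expect_error(reconstruct(mod, rep(1, n_modes(mod) + 1)), "exceeds")
})

test_that("sampling is seeded, deterministic and variance-faithful", {
  X <- rand_centered_matrix(m = 10, n = 8, seed = 51)
  mod <- shape_model(X)
  a <- sample_shape(mod, nsim = 3, seed = 7)
  b <- sample_shape(mod, nsim = 3, seed = 7)
  expect_identical(a, b)
  expect_error(sample_shape(mod, ncomp = 0), "ncomp")
  big <- sample_shape(mod, nsim = 10000, ncomp = 2, seed = 77)
  expect_equal(var(big$coefficients[1, ]), mod$eigenvalues[1], tolerance = 0.05)
  # modes beyond ncomp are not excited
  expect_equal(nrow(big$coefficients), 2L)
})

test_that("compactness is the cumulative eigenvalue share", {
  fake <- structure(list(eigenvalues = c(1, 1, 1, 1), n_train = 5L),
                    class = "shape_model")
  expect_equal(compactness(fake, 1), 0.25)
  expect_equal(compactness(fake), c(0.25, 0.5, 0.75, 1))
  X <- rand_centered_matrix(m = 10, n = 7, seed = 61)
  mod <- shape_model(X)
  cc <- compactness(mod)
  expect_true(all(diff(cc) >= 0))
  expect_equal(cc[n_modes(mod)], 1)
  expect_error(compactness(mod, 0), "k must")
})

test_that("mode sweeps span symmetric plausible displacements", {
  X <- rand_centered_matrix(m = 12, n = 6, seed = 71)
  mod <- shape_model(X)
  sw <- mode_sweep(mod, mode = 1, n_steps = 5)
  expect_equal(sw$b_values[3], 0)
  expect_equal(sw$shapes[, 3], mod$mean)
  expect_equal(sw$displacements[, 3], rep(0, 12))
  # endpoints mirror around the mean
  expect_equal(sw$shapes[, 5] - mod$mean, -(sw$shapes[, 1] - mod$mean))
  # max displacement = 3 sd(mode) * largest per-point norm of the eigenvector
  phi_pt <- sqrt(colSums(matrix(mod$components[, 1], nrow = 3)^2))
  expect_equal(max(sw$displacements[, 5]),
               3 * sqrt(mod$eigenvalues[1]) * max(phi_pt), tolerance = 1e-12)
  expect_error(mode_sweep(mod, mode = 99), "mode index")
})
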