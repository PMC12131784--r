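#' Fit a statistical shape model by PCA
#'
#' Builds a point-distribution model from a cohort of corresponded,
#' per-body-centred shape vectors: the model is the training mean shape
#' together with the orthonormal eigenvectors (modes of variation) and
#' eigenvalues of the sample covariance of the training vectors. A training
#' set of n samples yields at most n - 1 non-trivial modes. The data are not
#' rescaled, so overall size variation remains in the model, and they must
#' already be centred per body (centering is a translation and is checked,
#' not silently applied).
#'
#' New shapes are produced as `y = mean + components %*% b`, with the model
#' coefficients assumed independent Gaussian, `b_i ~ N(0, lambda_i)`.
#'
#' The decomposition is computed by thin SVD of the centred data matrix;
#' eigenvalues use the 1/(n-1) sample-covariance convention, applied
#' consistently in sampling, clipping and the chi-squared plausibility bound
#' so that every reported ratio is convention-invariant. Each eigenvector's
#' sign is fixed so that its largest-magnitude entry is positive.
#'
#' @param x a [shape_cohort], or a numeric 3m x n matrix whose columns are
#'   per-body-centred shape vectors.
#' @param bodies which bodies of the cohort to model (default all, in cohort
#'   order); more than one body gives a combined multi-body model.
#' @param layout a [block_layout] describing `x` when `x` is a matrix.
#' @param trivial_tol eigenvalues below `trivial_tol * lambda_1` are
#'   discarded as numerically trivial.
#' @param center_tol maximum tolerated per-body centroid norm (mm) of the
#'   inputs before an error is raised.
#' @return An object of class `shape_model`: a list with `mean` (3m vector),
#'   `components` (3m x r orthonormal matrix), `eigenvalues` (length r,
#'   non-increasing, mm^2), `n_train`, `layout` and `subjects`.
#' @examples
#' spec <- synthetic_cohort_spec(n_subjects = 12, m_per_body = c(plate = 40, stem = 38),
#'                               seed = 1)
#' co <- generate_cohort(spec)
#' mod <- shape_model(co)
#' mod
#' compactness(mod, 3)
#' @export
shape_model <- function(x, bodies = NULL, layout = NULL,
                        trivial_tol = 1e-10, center_tol = 1e-6) {
  subjects <- NULL
  if (inherits(x, "shape_cohort")) {
    if (is.null(bodies)) bodies <- names(x$bodies)
    cm <- cohort_matrix(x, bodies)
    subjects <- x$subjects
    X <- cm$X
    layout <- cm$layout
  } else {
    X <- as.matrix(x)
    if (is.null(layout))
      layout <- block_layout(stats::setNames(nrow(X) %/% 3L, "body"))
  }
  n <- ncol(X)
  if (n < 2L) stop("model building needs at least 2 training shapes")
  if (nrow(X) != layout$last[nrow(layout)])
    stop("data matrix rows do not match the block layout")
  # inputs must arrive centred per body: centering is the caller's statement
  # that pose has been removed, so a violation is an error, not a fix-up
  for (b in layout$body) {
    rows <- block_rows(layout, b)
    cent <- vapply(seq_len(n), function(j) {
      v <- matrix(X[rows, j], nrow = 3L)
      sqrt(sum(rowMeans(v)^2))
    }, numeric(1))
    if (any(cent > center_tol))
      stop(sprintf("body '%s' is not centred (max centroid norm %.3g mm > %.3g)",
                   b, max(cent), center_tol))
  }
  mean_shape <- rowMeans(X)
  Xc <- X - mean_shape
  sv <- svd(Xc, nu = min(n, nrow(X)), nv = 0)
  lambda <- sv$d^2 / (n - 1)
  r_max <- min(n - 1L, nrow(X))
  keep <- seq_len(r_max)
  if (lambda[1] > 0)
    keep <- keep[lambda[keep] > trivial_tol * lambda[1]]
  else
    keep <- integer(0)
  Phi <- sv$u[, keep, drop = FALSE]
  lambda <- lambda[keep]
  # deterministic sign: largest-|entry| of each column positive
  if (ncol(Phi) > 0) {
    flip <- vapply(seq_len(ncol(Phi)), function(j) {
      col <- Phi[, j]
      sign(col[which.max(abs(col))])
    }, numeric(1))
    Phi <- sweep(Phi, 2L, flip, "*")
  }
  structure(list(mean = mean_shape,
                 components = Phi,
                 eigenvalues = lambda,
                 n_train = n,
                 layout = layout,
                 subjects = subjects),
            class = "shape_model")
}

n_modes <- function(model) length(model$eigenvalues)

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("Statistical shape model (%s)\n",
              paste(x$layout$body, collapse = " + ")))
  cat(sprintf("  training shapes : %d\n", x$n_train))
  cat(sprintf("  points          : %s\n",
              paste(sprintf("%s=%d", x$layout$body, x$layout$m), collapse = ", ")))
  cat(sprintf("  modes retained  : %d\n", n_modes(x)))
  if (n_modes(x) > 0)
    cat(sprintf("  leading eigenvalues (mm^2): %s\n",
                paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", ")))
  invisible(x)
}

#' @export
summary.shape_model <- function(object, ...) {
  r <- n_modes(object)
  tab <- data.frame(mode = seq_len(r),
                    eigenvalue = object$eigenvalues,
                    sd = sqrt(object$eigenvalues),
                    var_share = object$eigenvalues / sum(object$eigenvalues),
                    compactness = compactness(object))
  structure(list(model = object, modes = tab), class = "summary.shape_model")
}

#' @export
print.summary.shape_model <- function(x, ...) {
  print(x$model)
  cat("\nModes of variation:\n")
  tab <- x$modes
  tab$eigenvalue <- signif(tab$eigenvalue, 4)
  tab$sd <- signif(tab$sd, 4)
  tab$var_share <- round(tab$var_share, 4)
  tab$compactness <- round(tab$compactness, 4)
  print(utils::head(tab, 15), row.names = FALSE)
  if (nrow(tab) > 15) cat("  ...", nrow(tab) - 15, "further modes\n")
  invisible(x)
}

#' @export
plot.shape_model <- function(x, ...) {
  r <- n_modes(x)
  if (r == 0L) stop("model has no non-trivial modes to plot")
  graphics::plot(seq_len(r), compactness(x), type = "b", pch = 16,
                 xlab = "number of principal components k",
                 ylab = "compactness c(k)",
                 ylim = c(0, 1), ...)
  graphics::abline(h = 0.9, lty = 3)
  invisible(x)
}

#' Project a shape onto a model's principal components
#'
#' Computes the raw (unregularized) model coefficients of a target shape,
#' `b = t(components) %*% (x - mean)`, using the leading `ncomp` modes, along
#' with the out-of-span projection residual.
#'
#' @param model a [shape_model].
#' @param x a shape vector of matching length (per-body centred).
#' @param ncomp number of leading modes to use (default: all retained).
#' @return A list with `b` (length-`ncomp` coefficients) and `residual_norm`
#'   (Euclidean norm of the part of `x - mean` outside the model span).
#' @export
fit_params <- function(model, x, ncomp = NULL) {
  x <- as_shape_vec(x)
  if (length(x) != length(model$mean))
    stop("shape vector length ", length(x), " does not match model (",
         length(model$mean), ")")
  r <- n_modes(model)
  if (is.null(ncomp)) ncomp <- r
  if (ncomp < 1L || ncomp > r) stop("ncomp must be in 1..", r)
  xc <- x - model$mean
  Phi <- model$components[, seq_len(ncomp), drop = FALSE]
  b <- drop(crossprod(Phi, xc))
  res <- xc - Phi %*% b
  list(b = b, residual_norm = sqrt(sum(res^2)))
}

#' Regularize model coefficients into the plausibility ellipsoid
#'
#' Applies the two-step plausibility filter: each coefficient is first
#' clipped into `[-clip_mult * sqrt(lambda_i), clip_mult * sqrt(lambda_i)]`,
#' then the uniform scale factor s closest to 1 is applied such that the
#' Mahalanobis sum `sum((s b_i)^2 / lambda_i)` does not exceed the
#' chi-squared quantile `qchisq(level, df)` — the Mahalanobis hyperellipsoid
#' of acceptable plausibility under `b_i ~ N(0, lambda_i)`. Minimizing
#' `(s - 1)^2` under this single quadratic constraint admits the closed form
#' `s = min(1, sqrt(qchisq(level, df) / Q))` with Q the post-clip sum.
#'
#' @param model a [shape_model].
#' @param b raw coefficients over the leading `length(b)` modes.
#' @param level certainty level of the chi-squared bound (default 0.997).
#' @param clip_mult per-mode clip bound in units of mode standard deviation
#'   (default 3).
#' @param df degrees of freedom of the chi-squared bound; defaults to
#'   `n_train - 1`.
#' @return An object of class `ssm_fit`: list with `b_raw`, `b_hat`
#'   (regularized coefficients), `scale_s`, `reconstruction` (shape vector
#'   `mean + components %*% b_hat`), `mahalanobis_q` and `plausibility`
#'   (`1 - pchisq(mahalanobis_q, df)`).
#' @export
regularize_params <- function(model, b, level = 0.997, clip_mult = 3,
                              df = NULL) {
  r <- n_modes(model)
  k <- length(b)
  if (k < 1L || k > r) stop("coefficient length must be in 1..", r)
  lambda <- model$eigenvalues[seq_len(k)]
  if (any(lambda <= 0)) stop("non-positive eigenvalue in scope")
  if (is.null(df)) df <- model$n_train - 1L
  if (df <= 0) stop("chi-squared degrees of freedom must be positive")
  bound <- clip_mult * sqrt(lambda)
  b_clip <- pmin(pmax(b, -bound), bound)
  q_clip <- sum(b_clip^2 / lambda)
  q_max <- stats::qchisq(level, df)
  s <- if (q_clip > q_max) sqrt(q_max / q_clip) else 1
  b_hat <- s * b_clip
  q_hat <- sum(b_hat^2 / lambda)
  structure(list(b_raw = b, b_hat = b_hat, scale_s = s,
                 reconstruction = reconstruct(model, b_hat),
                 mahalanobis_q = q_hat,
                 plausibility = 1 - stats::pchisq(q_hat, df),
                 df = df, level = level, clip_mult = clip_mult),
            class = "ssm_fit")
}

#' @export
print.ssm_fit <- function(x, ...) {
  cat(sprintf("Shape-model fit: %d coefficients, scale s = %.6g\n",
              length(x$b_hat), x$scale_s))
  cat(sprintf("  Mahalanobis sum %.4g (chi-squared_%g bound %.4g), plausibility %.4g\n",
              x$mahalanobis_q, x$df, stats::qchisq(x$level, x$df),
              x$plausibility))
  invisible(x)
}

#' @export
coef.ssm_fit <- function(object, ...) object$b_hat

#' Reconstruct a shape from model coefficients
#'
#' `y = mean + components[, 1:k] %*% b` for `k = length(b)`.
#'
#' @param model a [shape_model].
#' @param b coefficients over the leading `length(b)` modes (at most the
#'   number of retained modes).
#' @return A shape vector.
#' @export
reconstruct <- function(model, b) {
  k <- length(b)
  if (k > n_modes(model))
    stop("coefficient length ", k, " exceeds the ", n_modes(model),
         " retained modes")
  if (k == 0L) return(model$mean)
  drop(model$mean + model$components[, seq_len(k), drop = FALSE] %*% b)
}

#' Sample random shapes from a model
#'
#' Draws coefficients `b_i ~ N(0, lambda_i)` independently for the leading
#' `ncomp` modes (zero beyond) and reconstructs the corresponding shapes.
#'
#' @param model a [shape_model].
#' @param nsim number of shapes to draw.
#' @param ncomp number of leading modes sampled (default all retained).
#' @param seed optional integer seed; the caller's RNG state is untouched.
#' @return A list with `shapes` (3m x nsim matrix of shape vectors) and
#'   `coefficients` (ncomp x nsim matrix of the sampled b).
#' @export
sample_shape <- function(model, nsim = 1L, ncomp = NULL, seed = NULL) {
  r <- n_modes(model)
  if (r == 0L) stop("model has no non-trivial modes to sample")
  if (is.null(ncomp)) ncomp <- r
  if (ncomp < 1L || ncomp > r) stop("ncomp must be in 1..", r)
  if (nsim < 1L) stop("nsim must be at least 1")
  sds <- sqrt(model$eigenvalues[seq_len(ncomp)])
  B <- with_seed(seed,
    matrix(stats::rnorm(ncomp * nsim, sd = rep(sds, times = nsim)),
           nrow = ncomp))
  shapes <- model$mean + model$components[, seq_len(ncomp), drop = FALSE] %*% B
  list(shapes = shapes, coefficients = B)
}

#' @rdname sample_shape
#' @param object a [shape_model].
#' @param ... unused.
#' @return `simulate()` returns the 3m x nsim matrix of sampled shape
#'   vectors with the sampled coefficients as attribute `"coefficients"`.
#' @export
simulate.shape_model <- function(object, nsim = 1, seed = NULL, ncomp = NULL,
                                 ...) {
  s <- sample_shape(object, nsim = nsim, ncomp = ncomp, seed = seed)
  structure(s$shapes, coefficients = s$coefficients)
}

#' Model compactness
#'
#' The proportion of total training-set variance described by the leading k
#' principal components: `c(k) = sum(lambda[1:k]) / sum(lambda)`. It is
#' non-decreasing in k and reaches 1 at the last retained mode.
#'
#' @param model a [shape_model].
#' @param k number(s) of leading components; default all `1:r`.
#' @return Numeric vector of compactness values in `[0, 1]`.
#' @export
compactness <- function(model, k = NULL) {
  r <- n_modes(model)
  if (r == 0L) stop("model has no non-trivial modes")
  if (is.null(k)) k <- seq_len(r)
  if (any(k < 1L | k > r)) stop("k must be in 1..", r)
  cumsum(model$eigenvalues)[k] / sum(model$eigenvalues)
}

#' Sweep one mode of variation
#'
#' Generates the family of shapes `mean + phi_i * b` for evenly spaced
#' coefficient values spanning `±range_mult * sqrt(lambda_i)` — the feasible
#' single-mode range under the plausibility assumption — together with the
#' per-point displacement magnitudes relative to the mean shape.
#'
#' @param model a [shape_model].
#' @param mode mode index (1-based).
#' @param n_steps number of evenly spaced coefficient values (>= 2).
#' @param range_mult sweep half-range in units of the mode standard
#'   deviation (default 3).
#' @return A list with `b_values` (length `n_steps`), `shapes`
#'   (3m x n_steps), and `displacements` (m_total x n_steps per-point
#'   Euclidean displacement magnitudes from the mean).
#' @export
mode_sweep <- function(model, mode, n_steps = 7L, range_mult = 3) {
  r <- n_modes(model)
  if (mode < 1L || mode > r) stop("mode index must be in 1..", r)
  if (n_steps < 2L) stop("n_steps must be at least 2")
  half <- range_mult * sqrt(model$eigenvalues[mode])
  b_values <- seq(-half, half, length.out = n_steps)
  phi <- model$components[, mode]
  shapes <- model$mean + outer(phi, b_values)
  disp <- vapply(seq_len(n_steps), function(j)
    point_distances(shapes[, j], model$mean), numeric(length(phi) %/% 3L))
  list(b_values = b_values, shapes = shapes, displacements = disp)
}

#' Represent a target shape with a shape model
#'
#' Projects a target shape onto the model's leading modes, optionally applies
#' the plausibility regularization (clip to `±3 sqrt(lambda_i)` then uniform
#' scaling into the chi-squared Mahalanobis ellipsoid), and reconstructs the
#' model's representation of the target.
#'
#' @param object a [shape_model].
#' @param newdata a shape vector (or [point_cloud] for single-body models),
#'   or a 3m x n matrix of column shape vectors.
#' @param ncomp number of leading modes used (default all retained).
#' @param regularize apply the plausibility filter (default `TRUE`).
#' @param level,clip_mult regularization parameters, see
#'   [regularize_params()].
#' @param ... unused.
#' @return An `ssm_fit` (see [regularize_params()]), or a list of them for
#'   matrix `newdata`. With `regularize = FALSE` the fit carries
#'   `b_hat = b_raw` and `scale_s = 1`.
#' @export
predict.shape_model <- function(object, newdata, ncomp = NULL,
                                regularize = TRUE, level = 0.997,
                                clip_mult = 3, ...) {
  if (is.matrix(newdata) && !inherits(newdata, "point_cloud")) {
    return(lapply(seq_len(ncol(newdata)), function(j)
      predict(object, newdata[, j], ncomp = ncomp, regularize = regularize,
              level = level, clip_mult = clip_mult)))
  }
  fp <- fit_params(object, newdata, ncomp = ncomp)
  if (regularize) {
    fit <- regularize_params(object, fp$b, level = level,
                             clip_mult = clip_mult)
  } else {
    df <- object$n_train - 1L
    q <- sum(fp$b^2 / object$eigenvalues[seq_along(fp$b)])
    fit <- structure(list(b_raw = fp$b, b_hat = fp$b, scale_s = 1,
                          reconstruction = reconstruct(object, fp$b),
                          mahalanobis_q = q,
                          plausibility = 1 - stats::pchisq(q, df),
                          df = df, level = level, clip_mult = clip_mult),
                     class = "ssm_fit")
  }
  fit$residual_norm <- fp$residual_norm
  fit
}
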