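#' Validation reports
#'
#' All validation procedures return a `ssm_validation` data frame with one
#' row per test observation and columns `procedure`, `k` (the varied design
#' parameter), `fold` (left-out subject or draw index), `n_components`
#' (modes actually used), `d_avg` and `d_hausdorff` (mm, model output vs
#' target), and — where a training-mean baseline applies — `baseline_d_avg`
#' and `baseline_d_hausdorff` (training mean vs target). `summary()`
#' aggregates per (procedure, k) to median, quartiles, IQR and mean.
#'
#' @name ssm_validation
NULL

validation_report <- function(records) {
  df <- do.call(rbind, records)
  rownames(df) <- NULL
  class(df) <- c("ssm_validation", "data.frame")
  df
}

#' @export
summary.ssm_validation <- function(object, ...) {
  key <- interaction(object$procedure, object$k, drop = TRUE)
  out <- do.call(rbind, lapply(split(object, key), function(g) {
    q <- stats::quantile(g$d_avg, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(procedure = g$procedure[1], k = g$k[1], n_obs = nrow(g),
               d_avg_median = q[2], d_avg_q25 = q[1], d_avg_q75 = q[3],
               d_avg_iqr = q[3] - q[1], d_avg_mean = mean(g$d_avg),
               d_hausdorff_median = stats::median(g$d_hausdorff))
  }))
  out <- out[order(out$procedure, out$k), ]
  rownames(out) <- NULL
  out
}

#' @export
print.ssm_validation <- function(x, ...) {
  cat(sprintf("Shape-model validation report: %d observations (%s)\n",
              nrow(x), paste(unique(x$procedure), collapse = ", ")))
  print(utils::head(summary(x), 20))
  invisible(x)
}

# distances of a reconstruction and the training-mean baseline to a target
fold_record <- function(procedure, k, fold, n_comp, y, target, baseline) {
  data.frame(procedure = procedure, k = k, fold = fold,
             n_components = n_comp,
             d_avg = avg_point_distance(y, target),
             d_hausdorff = hausdorff_distance(y, target),
             baseline_d_avg = if (is.null(baseline)) NA_real_ else
               avg_point_distance(baseline, target),
             baseline_d_hausdorff = if (is.null(baseline)) NA_real_ else
               hausdorff_distance(baseline, target))
}

#' Leave-one-out ground-truth accuracy
#'
#' For each subject, a model is rebuilt on the other n - 1 subjects, the
#' left-out shape is fitted with all (n - 1) - 1 non-trivial components,
#' regularized into the plausibility ellipsoid, and reconstructed; the
#' average Euclidean point distance and Hausdorff metric between the
#' reconstruction and the target are recorded, alongside the distances from
#' the training-set mean to the target (the share of accuracy attributable
#' to the mean alone).
#'
#' @param cohort a [shape_cohort].
#' @param bodies which bodies to model (default: all, giving the combined
#'   model for multi-body cohorts).
#' @param level,clip_mult regularization parameters, see
#'   [regularize_params()].
#' @return An [ssm_validation] data frame with one row per fold.
#' @export
loo_ground_truth <- function(cohort, bodies = NULL, level = 0.997,
                             clip_mult = 3) {
  stopifnot(inherits(cohort, "shape_cohort"))
  if (is.null(bodies)) bodies <- names(cohort$bodies)
  n <- length(cohort$subjects)
  if (n < 3L) stop("leave-one-out needs at least 3 subjects")
  full <- cohort_matrix(cohort, bodies)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    model <- tryCatch(
      shape_model(cohort_subset(cohort, setdiff(seq_len(n), i)), bodies),
      error = function(e) stop("degenerate model in fold ", i, ": ",
                               conditionMessage(e)))
    if (n_modes(model) == 0L)
      stop("degenerate model in fold ", i, ": no non-trivial modes")
    target <- full$X[, i]
    fit <- predict(model, target, regularize = TRUE, level = level,
                   clip_mult = clip_mult)
    records[[i]] <- fold_record("loo", n_modes(model), i, n_modes(model),
                                fit$reconstruction, target, model$mean)
  }
  validation_report(records)
}

#' Generalization ability across training-set size
#'
#' Leave-one-out cross-validation repeated across training sample sizes k:
#' for each k and each left-out subject, the model is trained on k subjects
#' sampled without replacement from the remaining n - 1 and the left-out
#' shape is fitted with all k - 1 non-trivial components (regularized). One
#' random subset is drawn per (k, fold); at k = n - 1 the subset is the
#' whole remainder and the procedure reduces to [loo_ground_truth()].
#'
#' @param cohort a [shape_cohort].
#' @param bodies which bodies to model.
#' @param sizes training-set sizes to test (default `2:(n-1)`).
#' @param seed master seed; per-(k, fold) child seeds are derived
#'   deterministically.
#' @param level,clip_mult regularization parameters.
#' @return An [ssm_validation] data frame, n rows per size.
#' @export
generalization_by_samples <- function(cohort, bodies = NULL, sizes = NULL,
                                      seed = 1L, level = 0.997,
                                      clip_mult = 3) {
  stopifnot(inherits(cohort, "shape_cohort"))
  if (is.null(bodies)) bodies <- names(cohort$bodies)
  n <- length(cohort$subjects)
  if (is.null(sizes)) sizes <- 2:(n - 1L)
  if (any(sizes < 2L) || any(sizes > n - 1L))
    stop("training sizes must lie in 2..n-1")
  full <- cohort_matrix(cohort, bodies)
  records <- list()
  for (k in sizes) {
    for (i in seq_len(n)) {
      pool <- setdiff(seq_len(n), i)
      train <- if (k == n - 1L) pool else
        with_seed(child_seed(seed, 1L, k, i), sort(sample(pool, k)))
      model <- shape_model(cohort_subset(cohort, train), bodies)
      target <- full$X[, i]
      fit <- predict(model, target, regularize = TRUE, level = level,
                     clip_mult = clip_mult)
      records[[length(records) + 1L]] <-
        fold_record("generalization_samples", k, i, n_modes(model),
                    fit$reconstruction, target, model$mean)
    }
  }
  validation_report(records)
}

#' Generalization ability across number of principal components
#'
#' Full leave-one-out cross-validation repeated across the number of leading
#' principal components k retained when fitting the left-out shape (the
#' training set is always the full n - 1 remainder). At k = n - 2 — all
#' non-trivial components of the reduced training set — the procedure equals
#' [loo_ground_truth()] exactly.
#'
#' @param cohort a [shape_cohort].
#' @param bodies which bodies to model.
#' @param ks numbers of components to test (default `1:(n-2)`).
#' @param level,clip_mult regularization parameters.
#' @return An [ssm_validation] data frame, n rows per k.
#' @export
generalization_by_components <- function(cohort, bodies = NULL, ks = NULL,
                                         level = 0.997, clip_mult = 3) {
  stopifnot(inherits(cohort, "shape_cohort"))
  if (is.null(bodies)) bodies <- names(cohort$bodies)
  n <- length(cohort$subjects)
  if (n < 3L) stop("leave-one-out needs at least 3 subjects")
  if (is.null(ks)) ks <- seq_len(n - 2L)
  full <- cohort_matrix(cohort, bodies)
  records <- list()
  for (i in seq_len(n)) {
    model <- shape_model(cohort_subset(cohort, setdiff(seq_len(n), i)), bodies)
    if (any(ks > n_modes(model)))
      stop("k exceeds the ", n_modes(model), " non-trivial modes of fold ", i)
    target <- full$X[, i]
    for (k in ks) {
      fit <- predict(model, target, ncomp = k, regularize = TRUE,
                     level = level, clip_mult = clip_mult)
      records[[length(records) + 1L]] <-
        fold_record("generalization_components", k, i, k,
                    fit$reconstruction, target, model$mean)
    }
  }
  out <- validation_report(records)
  out[order(out$k, out$fold), ]
}

#' Model specificity
#'
#' Draws M random shapes from the model (coefficients `b_i ~ N(0,
#' lambda_i)` over the leading k modes) and records, for each, the average
#' Euclidean point distance to the closest training-set member (minimum
#' over the training set) and the Hausdorff metric to that member —
#' repeated across numbers of included components k. Low distances mean the
#' model generates only shapes resembling the training population.
#'
#' @param model a [shape_model].
#' @param training 3m x n matrix of the training shape vectors.
#' @param M number of random draws per k (study-scale default 10,000).
#' @param ks numbers of leading modes to test (default `1:r`).
#' @param seed master seed.
#' @param hausdorff also compute the Hausdorff metric to the closest member
#'   (the costly part; `TRUE` by default).
#' @return An [ssm_validation] data frame, M rows per k (`fold` = draw
#'   index; baselines are `NA`).
#' @export
specificity_test <- function(model, training, M = 10000L, ks = NULL,
                             seed = 1L, hausdorff = TRUE) {
  stopifnot(inherits(model, "shape_model"))
  training <- as.matrix(training)
  if (ncol(training) < 1L) stop("empty training set")
  if (nrow(training) != length(model$mean))
    stop("training matrix rows do not match the model")
  if (M < 1L) stop("M must be at least 1")
  r <- n_modes(model)
  if (r == 0L) stop("model has no non-trivial modes")
  if (is.null(ks)) ks <- seq_len(r)
  m <- nrow(training) %/% 3L
  pt_group <- rep(seq_len(m), each = 3L)
  records <- list()
  for (k in ks) {
    draws <- sample_shape(model, nsim = M, ncomp = k,
                          seed = child_seed(seed, 2L, k))$shapes
    # average point distance of every draw to every training member
    dmat <- vapply(seq_len(ncol(training)), function(j) {
      D2 <- (draws - training[, j])^2
      colMeans(sqrt(rowsum(D2, pt_group)))
    }, numeric(M))
    dmat <- matrix(dmat, nrow = M)
    closest <- max.col(-dmat, ties.method = "first")
    d_min <- dmat[cbind(seq_len(M), closest)]
    d_h <- if (hausdorff) vapply(seq_len(M), function(s)
      hausdorff_distance(draws[, s], training[, closest[s]]), numeric(1))
      else rep(NA_real_, M)
    records[[length(records) + 1L]] <-
      data.frame(procedure = "specificity", k = k, fold = seq_len(M),
                 n_components = k, d_avg = d_min, d_hausdorff = d_h,
                 baseline_d_avg = NA_real_, baseline_d_hausdorff = NA_real_)
  }
  validation_report(records)
}
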