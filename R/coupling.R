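#' Split a combined model into per-body blocks
#'
#' Row-partitions the combined model's mean and eigenvector matrix by its
#' block layout: for a scapula+humerus model this yields the upper portion
#' `Phi_CS` and lower portion `Phi_CH` of every combined eigenvector, plus
#' the per-body means. The split is lossless — stacking the blocks restores
#' the originals exactly — and, by orthonormality of the combined
#' eigenvectors, the squared block norms of each mode sum to 1.
#'
#' @param model a combined [shape_model] whose layout has >= 1 bodies.
#' @return Named list (one element per body) of lists with `body`, `rows`,
#'   `mean` (the body's block of the combined mean) and `components` (the
#'   body's rows of the combined eigenvector matrix).
#' @export
split_blocks <- function(model) {
  stopifnot(inherits(model, "shape_model"))
  if (is.null(model$layout)) stop("model has no block layout")
  out <- lapply(seq_len(nrow(model$layout)), function(i) {
    rows <- seq.int(model$layout$first[i], model$layout$last[i])
    list(body = model$layout$body[i], rows = rows,
         mean = model$mean[rows],
         components = model$components[rows, , drop = FALSE])
  })
  names(out) <- model$layout$body
  out
}

#' Decompose combined-model eigenvectors into single-body modes
#'
#' Expresses each combined-model eigenvector's block for one body as a
#' linear combination of that body's single-body eigenvectors:
#' `gamma_j = t(Phi_S) %*% phi_CS_j`. When both models are trained on the
#' same cohort the block lies in the single-body span and the reconstruction
#' residual vanishes. The weights are also converted to directionless
#' contribution proportions `A[j, i] = |gamma_j[i]| / sum(|gamma_j|)` — row
#' j of `A` says which single-body modes make up combined mode j.
#'
#' @param combined_model the combined [shape_model].
#' @param single_model the single-body [shape_model] of `body`, trained on
#'   the same cohort.
#' @param body body label identifying the block of the combined model.
#' @return An object of class `block_decomposition`: list with `gamma`
#'   (r_single x r_combined weight matrix, column j = gamma_j), `A`
#'   (r_combined x r_single contribution-proportion matrix, rows summing to
#'   1), `residuals` (per combined mode, norm of the block minus its
#'   single-body reconstruction) and `block_norm2` (squared block norm of
#'   each combined mode).
#' @export
decompose_combined_eigenvectors <- function(combined_model, single_model,
                                            body) {
  blocks <- split_blocks(combined_model)
  if (!body %in% names(blocks)) stop("body '", body, "' not in combined model")
  blk <- blocks[[body]]
  if (nrow(blk$components) != length(single_model$mean))
    stop("single-body model does not match the combined block size")
  gamma <- crossprod(single_model$components, blk$components)
  recon <- single_model$components %*% gamma
  residuals <- sqrt(colSums((recon - blk$components)^2))
  tot <- colSums(abs(gamma))
  if (any(tot == 0))
    stop("all-zero decomposition weights for combined mode(s) ",
         paste(which(tot == 0), collapse = ", "))
  A <- t(sweep(abs(gamma), 2L, tot, "/"))
  structure(list(body = body, gamma = gamma, A = A, residuals = residuals,
                 block_norm2 = colSums(blk$components^2)),
            class = "block_decomposition")
}

#' Attribute single-body variance to combined modes via decomposition weights
#'
#' Given the decomposition weights `gamma_j` of combined mode j in the
#' single-body eigenbasis and the single-body eigenvalue shares (proportions
#' of that body's total training variance), computes
#' `v_j = sum_i gamma_j[i]^2 * share_i` — the variance of the combined
#' mode's block direction expressed through the single-body spectrum. Each
#' `v_j` lies in `[0, 1]` and, because the weight-matrix rows have norm at
#' most 1, `sum_j v_j <= 1`.
#'
#' Note this weight-based attribution underweights modes whose block norm is
#' below 1 (the norm enters squared twice), so its cumulative total stays
#' below 1 even under complete coupling; [coupling_report()] therefore uses
#' the exact combined-eigenvalue bookkeeping for per-mode variance
#' attribution and reports both.
#'
#' @param gamma r_single x r_combined weight matrix (or a
#'   `block_decomposition`).
#' @param shares single-body eigenvalue shares, non-negative, summing to 1.
#' @return Numeric vector `v` over combined modes.
#' @export
variance_attribution <- function(gamma, shares) {
  if (inherits(gamma, "block_decomposition")) gamma <- gamma$gamma
  if (any(shares < 0)) stop("eigenvalue shares must be non-negative")
  if (abs(sum(shares) - 1) > 1e-6) stop("eigenvalue shares must sum to 1")
  if (length(shares) != nrow(gamma))
    stop("one share per single-body mode is required")
  drop(colSums(gamma^2 * shares))
}

#' Per-mode coupled variation
#'
#' The variation of two bodies that co-occurs along one combined mode is the
#' smaller of the two bodies' variance attributions for that mode:
#' `v_J[j] = min(v_body1[j], v_body2[j])`; the cumulative sum over modes is
#' the total coupled variation.
#'
#' @param v1,v2 per-combined-mode variance attributions of the two bodies
#'   (equal length).
#' @return List with `v_joint` and `cumulative`.
#' @export
coupled_variation <- function(v1, v2) {
  if (length(v1) != length(v2))
    stop("attribution vectors differ in length")
  vj <- pmin(v1, v2)
  list(v_joint = vj, cumulative = cumsum(vj))
}

#' Covariance of block contributions to combined-model coefficients
#'
#' The combined-model coefficients decompose into per-body contributions
#' `b_S = t(Phi_CS) %*% (x_S - mean_S)` and `b_H = t(Phi_CH) %*%
#' (x_H - mean_H)`, with `b = b_S + b_H`. Their cross-covariance equals
#' `t(Phi_CS) %*% Sigma_SH %*% Phi_CH` with `Sigma_SH` the cross-covariance
#' of the two bodies' training data; both the closed form and the empirical
#' covariance of the computed contributions are returned (they agree
#' algebraically), plus the heatmap-ready matrix `A_B` of absolute
#' covariances standardized to the largest element.
#'
#' @param cohort the [shape_cohort] the combined model was trained on.
#' @param combined_model the combined [shape_model].
#' @param bodies the two body labels (default: the model's first two
#'   blocks).
#' @return List with `contributions` (named list of r x n matrices),
#'   `cov_empirical`, `cov_closed_form` and `A_B`.
#' @export
contribution_covariance <- function(cohort, combined_model, bodies = NULL) {
  stopifnot(inherits(cohort, "shape_cohort"),
            inherits(combined_model, "shape_model"))
  n <- length(cohort$subjects)
  if (n < 3L) stop("contribution covariance needs at least 3 subjects")
  blocks <- split_blocks(combined_model)
  if (is.null(bodies)) bodies <- names(blocks)[1:2]
  if (length(bodies) != 2L || !all(bodies %in% names(blocks)))
    stop("two body labels present in the combined model are required")
  ctr <- lapply(bodies, function(b) {
    Xc <- cohort$bodies[[b]] - blocks[[b]]$mean
    list(Xc = Xc, B = crossprod(blocks[[b]]$components, Xc))
  })
  names(ctr) <- bodies
  emp <- tcrossprod(ctr[[1]]$B, ctr[[2]]$B) / (n - 1)
  sigma_12 <- tcrossprod(ctr[[1]]$Xc, ctr[[2]]$Xc) / (n - 1)
  closed <- crossprod(blocks[[bodies[1]]]$components,
                      sigma_12 %*% blocks[[bodies[2]]]$components)
  mx <- max(abs(emp))
  A_B <- if (mx > 0) abs(emp) / mx else abs(emp)
  list(contributions = lapply(ctr, `[[`, "B"),
       cov_empirical = emp, cov_closed_form = closed, A_B = A_B)
}

#' Quantify coupled two-body variation
#'
#' The full coupling analysis of a paired cohort: builds the two single-body
#' models and the combined model, decomposes every combined eigenvector's
#' body blocks into single-body modes (weights `gamma`, contribution
#' heatmaps `A`), attributes to each combined mode the exact proportion of
#' each body's training variance it describes
#' (`v_body[j] = lambda_C[j] * ||block_j||^2 / V_body`, which sums to 1 per
#' body), takes the per-mode minimum as the coupled variation `v_J`, and
#' computes the block-contribution covariance `A_B`. The weight-based
#' attribution of [variance_attribution()] is reported alongside as
#' `v_gamma`.
#'
#' @param cohort a two-body (or more) [shape_cohort].
#' @param bodies the two body labels to analyse (default: first two).
#' @return An object of class `coupling_report`: list with `models`
#'   (`single` per body and `combined`), `decompositions`, `v_body`
#'   (exact attributions per body), `v_gamma`, `v_joint`,
#'   `v_joint_cumulative` and `covariance` (from
#'   [contribution_covariance()]).
#' @examples
#' spec <- synthetic_cohort_spec(n_subjects = 16,
#'                               m_per_body = c(a = 30, b = 24),
#'                               coupling_fraction = 1, noise_sd = 0.02,
#'                               seed = 7)
#' rep <- coupling_report(generate_cohort(spec))
#' rep
#' @export
coupling_report <- function(cohort, bodies = NULL) {
  stopifnot(inherits(cohort, "shape_cohort"))
  if (is.null(bodies)) bodies <- names(cohort$bodies)[1:2]
  if (length(bodies) != 2L) stop("coupling analysis requires two bodies")
  singles <- lapply(bodies, function(b) shape_model(cohort, b))
  names(singles) <- bodies
  combined <- shape_model(cohort, bodies)
  lambda_c <- combined$eigenvalues
  decomp <- list()
  v_body <- list()
  v_gamma <- list()
  for (b in bodies) {
    dec <- decompose_combined_eigenvectors(combined, singles[[b]], b)
    V <- sum(singles[[b]]$eigenvalues)
    v_body[[b]] <- lambda_c * dec$block_norm2 / V
    v_gamma[[b]] <- variance_attribution(
      dec, singles[[b]]$eigenvalues / V)
    decomp[[b]] <- dec
  }
  cv <- coupled_variation(v_body[[bodies[1]]], v_body[[bodies[2]]])
  structure(list(bodies = bodies,
                 models = list(single = singles, combined = combined),
                 decompositions = decomp,
                 v_body = v_body,
                 v_gamma = v_gamma,
                 v_joint = cv$v_joint,
                 v_joint_cumulative = cv$cumulative,
                 covariance = contribution_covariance(cohort, combined,
                                                      bodies)),
            class = "coupling_report")
}

#' @export
print.coupling_report <- function(x, ...) {
  cat(sprintf("Coupled-variation report: %s + %s, %d combined modes\n",
              x$bodies[1], x$bodies[2], length(x$v_joint)))
  tot <- x$v_joint_cumulative[length(x$v_joint_cumulative)]
  cat(sprintf("  total coupled variation: %.1f%% of per-body variance\n",
              100 * tot))
  k <- min(6L, length(x$v_joint))
  tab <- data.frame(mode = seq_len(k),
                    v_1 = round(x$v_body[[1]][1:k], 4),
                    v_2 = round(x$v_body[[2]][1:k], 4),
                    v_joint = round(x$v_joint[1:k], 4))
  names(tab)[2:3] <- paste0("v_", x$bodies)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out prediction of a missing counterpart body
#'
#' Evaluates how well the combined model predicts one body's shape from its
#' partner. Per fold, the combined model is trained on the other n - 1
#' pairs; the per-body contributions `b_given = t(Phi_C,given) %*%
#' (x_given - mean_given)` and `b_target` are computed for the training set;
#' a random-forest regressor (one forest per output coordinate) learns
#' `b_given -> b_target`; the left-out subject's given-body contribution is
#' computed, the target contribution predicted, regularized with the usual
#' clip-then-scale plausibility filter, and the target body
#' reconstructed as `mean_target + Phi_C,target %*% b_hat`. The filter's
#' per-mode variances are the sample variances of the training-set target
#' contributions (not the combined-model eigenvalues: block contributions
#' of near-null combined modes are large and anticancel between the bodies,
#' so their variance far exceeds the combined eigenvalue and a
#' lambda_C-based ellipsoid would reject even the true contribution
#' vector). The baseline
#' prediction is the training-set mean of the target body — the best
#' estimate available to independent single-body models, for which
#' `E(x_2 | x_1) = mean(x_2)`.
#'
#' @param cohort a paired [shape_cohort].
#' @param given body label observed.
#' @param target body label to predict (must differ from `given`).
#' @param ntree trees per random forest (default 200).
#' @param seed master seed; per-fold child seeds are derived
#'   deterministically.
#' @param level,clip_mult regularization parameters.
#' @return A list with `report` (an [ssm_validation] data frame, one row per
#'   fold) and `predictions` (per fold: `b_given`, `b_predicted`,
#'   `prediction` shape vector).
#' @export
predict_counterpart_loo <- function(cohort, given, target, ntree = 200L,
                                    seed = 1L, level = 0.997, clip_mult = 3) {
  stopifnot(inherits(cohort, "shape_cohort"))
  if (identical(given, target))
    stop("given and target bodies must differ")
  for (b in c(given, target))
    if (!b %in% names(cohort$bodies)) stop("unknown body label: ", b)
  n <- length(cohort$subjects)
  if (n < 4L) stop("counterpart prediction needs at least 4 subjects")
  bodies <- intersect(names(cohort$bodies), c(given, target))  # cohort order
  records <- vector("list", n)
  preds <- vector("list", n)
  for (i in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), i)
    model <- shape_model(cohort_subset(cohort, train_idx), bodies)
    blocks <- split_blocks(model)
    Bg <- crossprod(blocks[[given]]$components,
                    cohort$bodies[[given]][, train_idx] - blocks[[given]]$mean)
    Bt <- crossprod(blocks[[target]]$components,
                    cohort$bodies[[target]][, train_idx] - blocks[[target]]$mean)
    b_given <- drop(crossprod(blocks[[given]]$components,
                              cohort$bodies[[given]][, i] -
                                blocks[[given]]$mean))
    r <- n_modes(model)
    b_pred <- vapply(seq_len(r), function(j) {
      rf <- with_seed(child_seed(seed, 3L, i, j),
                      randomForest::randomForest(x = t(Bg), y = Bt[j, ],
                                                 ntree = ntree))
      unname(stats::predict(rf, matrix(b_given, nrow = 1)))
    }, numeric(1))
    # clip-then-scale plausibility filter over the predicted contribution,
    # with per-mode variances of the contributions themselves
    lambda <- apply(Bt, 1L, stats::var)
    lambda <- pmax(lambda, 1e-12 * max(lambda))
    bound <- clip_mult * sqrt(lambda)
    b_clip <- pmin(pmax(b_pred, -bound), bound)
    q <- sum(b_clip^2 / lambda)
    q_max <- stats::qchisq(level, model$n_train - 1L)
    s <- if (q > q_max) sqrt(q_max / q) else 1
    b_hat <- s * b_clip
    y <- blocks[[target]]$mean +
      drop(blocks[[target]]$components %*% b_hat)
    truth <- cohort$bodies[[target]][, i]
    records[[i]] <- fold_record("counterpart", r, i, r, y, truth,
                                blocks[[target]]$mean)
    preds[[i]] <- list(b_given = b_given, b_predicted = b_hat,
                       scale_s = s, prediction = y)
  }
  list(report = validation_report(records), predictions = preds)
}
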