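# Shared fixtures: everything is generated in code under fixed seeds.

# random point cloud, optionally centred
rand_cloud <- function(m, seed, center = FALSE, scale = 10,
                       body = "body", subject = "s") {
  cl <- with_test_seed(seed,
    point_cloud(matrix(stats::rnorm(3 * m, sd = scale), m, 3), body, subject))
  if (center) center_cloud(cl) else cl
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

# matrix of n per-block-centred random shape vectors (single body, m points)
rand_centered_matrix <- function(m, n, seed, scale = 10) {
  with_test_seed(seed, {
    X <- matrix(stats::rnorm(3 * m * n, sd = scale), 3 * m, n)
    apply(X, 2L, function(v) {
      M <- matrix(v, nrow = 3L)
      as.vector(M - rowMeans(M))
    })
  })
}

# small two-body synthetic cohort
small_spec <- function(n = 12, m = c(plate = 30, stem = 26), f = 0.5,
                       noise = 0.05, seed = 1, q_shared = 2, q_own = 2, ...) {
  synthetic_cohort_spec(n_subjects = n, m_per_body = m,
                        coupling_fraction = f, noise_sd = noise,
                        q_shared = q_shared, q_own = q_own,
                        seed = seed, ...)
}

# brute-force per-point average distance
oracle_avg_dist <- function(A, B) {
  stopifnot(nrow(A) == nrow(B))
  mean(vapply(seq_len(nrow(A)), function(i)
    sqrt(sum((A[i, ] - B[i, ])^2)), numeric(1)))
}

# brute-force O(m^2) bidirectional Hausdorff
oracle_hausdorff <- function(A, B) {
  d <- function(P, Q) {
    max(vapply(seq_len(nrow(P)), function(i)
      min(vapply(seq_len(nrow(Q)), function(j)
        sqrt(sum((P[i, ] - Q[j, ])^2)), numeric(1))), numeric(1)))
  }
  max(d(A, B), d(B, A))
}
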