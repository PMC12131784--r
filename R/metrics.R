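#' Point-cloud distance measures
#'
#' The three measures used throughout model validation, all in millimetres.
#'
#' `rms_distance()` is the root-mean-square difference over all 3m vector
#' elements: `sqrt(mean((o - t)^2))`.
#'
#' `avg_point_distance()` is the mean over the m corresponding point pairs of
#' the Euclidean point-to-point distance; it has a direct interpretation as
#' the typical 3D error per correspondence point. By Jensen's inequality
#' (concavity of the square root) the mean per-point distance never exceeds
#' the root of the mean squared per-point distance.
#'
#' `hausdorff_distance()` is the bidirectional Hausdorff metric: the larger
#' of the two directed max-over-min nearest-neighbour distances. It ignores
#' correspondence order and the two clouds may have different point counts.
#'
#' @param o,t shape vectors (interleaved `[x1,y1,z1,...]` numeric vectors) or
#'   [point_cloud] objects. `rms_distance` and `avg_point_distance` require
#'   equal lengths and use the correspondence order.
#' @return A non-negative scalar distance in mm. All three are symmetric in
#'   `(o, t)` and zero when `o == t`.
#' @examples
#' a <- point_cloud(rbind(c(0, 0, 0), c(0, 0, 2)))
#' b <- point_cloud(rbind(c(0, 0, 0), c(0, 0, 0)))
#' avg_point_distance(a, b)  # (0 + 2) / 2 = 1
#' rms_distance(a, b)        # sqrt(4 / 6)
#' hausdorff_distance(a, b)  # 2
#' @name distances
NULL

as_shape_vec <- function(x) {
  if (inherits(x, "point_cloud")) vectorize(x) else as.numeric(x)
}

#' @rdname distances
#' @export
rms_distance <- function(o, t) {
  o <- as_shape_vec(o); t <- as_shape_vec(t)
  if (length(o) != length(t))
    stop("shape vectors differ in length: ", length(o), " vs ", length(t))
  sqrt(mean((o - t)^2))
}

# per-point Euclidean distances between two equal-length shape vectors
point_distances <- function(o, t) {
  d <- o - t
  m <- length(d) %/% 3L
  D <- matrix(d, nrow = 3L)
  sqrt(colSums(D^2))
}

#' @rdname distances
#' @export
avg_point_distance <- function(o, t) {
  o <- as_shape_vec(o); t <- as_shape_vec(t)
  if (length(o) != length(t))
    stop("shape vectors differ in length: ", length(o), " vs ", length(t))
  mean(point_distances(o, t))
}

#' @rdname distances
#' @export
hausdorff_distance <- function(o, t) {
  O <- if (inherits(o, "point_cloud")) unclass(o) else {
    o <- as.numeric(o)
    if (length(o) == 0L || length(o) %% 3L != 0L) stop("invalid point set")
    matrix(o, ncol = 3L, byrow = TRUE)
  }
  T_ <- if (inherits(t, "point_cloud")) unclass(t) else {
    t <- as.numeric(t)
    if (length(t) == 0L || length(t) %% 3L != 0L) stop("invalid point set")
    matrix(t, ncol = 3L, byrow = TRUE)
  }
  if (nrow(O) == 0L || nrow(T_) == 0L) stop("empty point cloud")
  max(directed_hausdorff(O, T_), directed_hausdorff(T_, O))
}

# Exact directed max-of-min nearest-neighbour distance, computed blockwise so
# the m1 x m2 distance matrix never exceeds ~8 MB at a time. The expansion
# |a|^2 + |b|^2 - 2 a.b only locates each row's nearest neighbour; the
# distance itself is recomputed by direct subtraction so cancellation error
# cannot leak into the result.
directed_hausdorff <- function(A, B, chunk = 1024L) {
  b2 <- rowSums(B^2)
  worst <- 0
  for (start in seq(1L, nrow(A), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(A))
    Ai <- A[idx, , drop = FALSE]
    d2 <- outer(rowSums(Ai^2), b2, "+") - 2 * tcrossprod(Ai, B)
    nn <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(rowSums((Ai - B[nn, , drop = FALSE])^2))
    worst <- max(worst, max(dmin))
  }
  worst
}
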