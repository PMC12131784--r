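#' Corresponded point clouds
#'
#' A point cloud is an ordered set of m three-dimensional correspondence
#' points in millimetres: the i-th point denotes the same anatomical location
#' on every subject, and no operation in this package ever permutes point
#' order.
#'
#' @param coords numeric m x 3 matrix (columns x, y, z, in mm) or anything
#'   coercible to one.
#' @param body_label identifier of the body the cloud belongs to, e.g.
#'   `"scapula"` or `"humerus"`.
#' @param subject_id identifier of the subject.
#' @return An object of class `point_cloud`: an m x 3 numeric matrix with
#'   attributes `body_label` and `subject_id`.
#' @examples
#' pc <- point_cloud(rbind(c(0, 0, 0), c(1, 2, 3)), "scapula", "s01")
#' n_points(pc)
#' @export
point_cloud <- function(coords, body_label = "body", subject_id = "subject") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L)
    stop("point cloud coordinates must have exactly 3 columns (x, y, z)")
  if (nrow(coords) < 1L)
    stop("point cloud must contain at least one point")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("point cloud contains non-finite coordinates")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(coords,
            body_label = as.character(body_label),
            subject_id = as.character(subject_id),
            class = c("point_cloud", "matrix", "array"))
}

#' @rdname point_cloud
#' @param x a `point_cloud`.
#' @export
n_points <- function(x) nrow(x)

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points, body '%s', subject '%s'\n",
              nrow(x), attr(x, "body_label"), attr(x, "subject_id")))
  cat(sprintf("  centroid (mm): [%.4g, %.4g, %.4g]\n",
              mean(x[, 1]), mean(x[, 2]), mean(x[, 3])))
  invisible(x)
}

#' Read a correspondence point cloud from disk
#'
#' Reads the whitespace-delimited `.particles` dialect (one `x y z` row per
#' point, no header; fields beyond the first three are ignored) or, for paths
#' ending in `.csv`, a comma-separated file with header `x,y,z`.
#'
#' @param path path to the file.
#' @param body_label,subject_id identifiers stored on the returned cloud.
#' @return A [point_cloud].
#' @seealso [write_particles()]
#' @export
read_particles <- function(path, body_label = "body", subject_id = "subject") {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    need <- c("x", "y", "z")
    if (!all(need %in% names(df)))
      stop("CSV point cloud must have header columns x,y,z: ", path)
    return(point_cloud(as.matrix(df[, need]), body_label, subject_id))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty point cloud file: ", path)
  line_no <- which(keep)
  coords <- matrix(NA_real_, nrow = length(lines), ncol = 3L)
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[[i]]), "[[:space:]]+")[[1]]
    if (length(fields) < 3L)
      stop(sprintf("parse error at line %d of %s: fewer than 3 fields",
                   line_no[i], path))
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals))
      stop(sprintf("parse error at line %d of %s: non-numeric coordinate",
                   line_no[i], path))
    coords[i, ] <- vals
  }
  point_cloud(coords, body_label, subject_id)
}

#' Write a correspondence point cloud to disk
#'
#' Writes the `.particles` dialect (one `x y z` row per point, no header) at
#' full double precision, or CSV with header `x,y,z` for paths ending in
#' `.csv`, so that [read_particles()] round-trips to at least 12 significant
#' digits.
#'
#' @param cloud a [point_cloud].
#' @param path destination path.
#' @return Invisibly, `path`.
#' @export
write_particles <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!dir.exists(dirname(path)))
    stop("cannot write point cloud, directory does not exist: ", dirname(path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- as.data.frame(unclass(cloud)[, , drop = FALSE])
    names(df) <- c("x", "y", "z")
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, row.names = FALSE, quote = FALSE)
  } else {
    rows <- apply(cloud, 1L, function(p)
      paste(sprintf("%.17g", p), collapse = " "))
    writeLines(rows, path)
  }
  invisible(path)
}

#' Centre a point cloud at the origin
#'
#' Translates the cloud so that its centroid is the origin. Centering is a
#' rigid translation: it changes position but not shape (all pairwise
#' inter-point distances are preserved), and is the preprocessing the shape
#' models require so that PCA captures shape rather than pose.
#'
#' @param cloud a [point_cloud].
#' @return The centred [point_cloud].
#' @export
center_cloud <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (!all(is.finite(cloud))) stop("non-finite coordinates in point cloud")
  ctr <- colMeans(cloud)
  point_cloud(sweep(unclass(cloud), 2L, ctr, "-"),
              attr(cloud, "body_label"), attr(cloud, "subject_id"))
}

#' Flatten a point cloud into a shape vector (and back)
#'
#' A shape vector is the point-major interleaved concatenation
#' `[x1, y1, z1, x2, y2, z2, ..., xm, ym, zm]` of the cloud's coordinates;
#' all model algebra operates on shape vectors. `vectorize()` and
#' `devectorize()` are mutually inverse.
#'
#' @param cloud a [point_cloud].
#' @return For `vectorize`, a numeric vector of length 3m. For `devectorize`,
#'   a [point_cloud].
#' @export
vectorize <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  as.vector(t(unclass(cloud)))
}

#' @rdname vectorize
#' @param vec numeric vector of length divisible by 3 in interleaved layout.
#' @param body_label,subject_id identifiers for the rebuilt cloud.
#' @export
devectorize <- function(vec, body_label = "body", subject_id = "subject") {
  vec <- as.numeric(vec)
  if (length(vec) %% 3L != 0L)
    stop("shape vector length must be divisible by 3, got ", length(vec))
  point_cloud(matrix(vec, ncol = 3L, byrow = TRUE), body_label, subject_id)
}

#' Block layout of a concatenated multi-body shape vector
#'
#' Records, for each body in a concatenated shape vector, its point count and
#' the contiguous run of vector indices it occupies. The ranges partition
#' `1:(3 * sum(m))` exactly, in the order the bodies were concatenated.
#'
#' @param m named integer vector of per-body point counts, in concatenation
#'   order.
#' @return A data frame of class `block_layout` with columns `body`, `m`,
#'   `first`, `last` (1-based inclusive vector index range).
#' @export
block_layout <- function(m) {
  if (length(m) < 1L) stop("block layout needs at least one body")
  if (is.null(names(m)) || any(!nzchar(names(m))))
    stop("per-body point counts must be named by body label")
  nm <- names(m)
  m <- as.integer(m)
  names(m) <- nm
  len <- 3L * m
  last <- cumsum(len)
  first <- last - len + 1L
  structure(data.frame(body = names(m), m = m, first = first, last = last,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("block_layout", "data.frame"))
}

#' @rdname block_layout
#' @param layout a `block_layout`.
#' @param body a body label present in the layout.
#' @return `block_rows()` returns the integer vector indices of that body's
#'   block.
#' @export
block_rows <- function(layout, body) {
  i <- match(body, layout$body)
  if (is.na(i)) stop("body '", body, "' not present in layout")
  seq.int(layout$first[i], layout$last[i])
}

#' Concatenate per-body shape vectors into one multi-body vector
#'
#' Stacks one shape vector per body, in the order supplied, into a single
#' combined vector (e.g. a 1600-point and a 1536-point body concatenate to a
#' 3(1600+1536) = 9408-element vector) and records the block layout.
#'
#' @param vecs named list of numeric shape vectors, one per body, each of
#'   length divisible by 3.
#' @return A list with elements `vector` (the concatenated shape vector) and
#'   `layout` (a [block_layout]).
#' @export
concatenate_bodies <- function(vecs) {
  if (length(vecs) < 1L) stop("need at least one body to concatenate")
  if (is.null(names(vecs)) || any(!nzchar(names(vecs))))
    stop("shape vectors must be named by body label")
  lens <- vapply(vecs, length, integer(1))
  if (any(lens %% 3L != 0L))
    stop("every per-body shape vector length must be divisible by 3")
  layout <- block_layout(lens %/% 3L)
  list(vector = unlist(vecs, use.names = FALSE), layout = layout)
}

#' Paired shape cohorts
#'
#' A cohort holds, for each of n subjects and each body, one corresponded
#' point cloud; within a body every subject has the same point count. The
#' clouds are stored columnwise as shape vectors, ready for model building.
#'
#' @param clouds a list of [point_cloud] objects covering every
#'   (subject, body) combination exactly once.
#' @param center if `TRUE` (default) each cloud is centred at the origin.
#' @return An object of class `shape_cohort`: a list with `subjects`
#'   (character vector), `m` (named per-body point counts) and `bodies`
#'   (named list of 3m x n shape-vector matrices, columns = subjects).
#' @examples
#' cl <- lapply(1:3, function(i)
#'   point_cloud(matrix(rnorm(30), 10, 3), "plate", paste0("s", i)))
#' co <- shape_cohort(cl)
#' co
#' @export
shape_cohort <- function(clouds, center = TRUE) {
  stopifnot(length(clouds) >= 1L,
            all(vapply(clouds, inherits, logical(1), "point_cloud")))
  subj <- vapply(clouds, attr, character(1), "subject_id")
  body <- vapply(clouds, attr, character(1), "body_label")
  subjects <- unique(subj)
  bodies <- unique(body)
  if (length(subjects) < 2L) stop("a cohort needs at least 2 subjects")
  mats <- list()
  ms <- integer(0)
  for (b in bodies) {
    idx <- which(body == b)
    if (!setequal(subj[idx], subjects) || length(idx) != length(subjects))
      stop("every subject must be present exactly once for body '", b, "'")
    idx <- idx[match(subjects, subj[idx])]
    m <- unique(vapply(clouds[idx], nrow, integer(1)))
    if (length(m) != 1L)
      stop("inconsistent point count across subjects for body '", b, "'")
    cols <- vapply(clouds[idx], function(cl) {
      if (center) cl <- center_cloud(cl)
      vectorize(cl)
    }, numeric(3L * m))
    mats[[b]] <- cols
    ms[b] <- m
  }
  structure(list(subjects = subjects, m = ms, bodies = mats),
            class = "shape_cohort")
}

#' @export
print.shape_cohort <- function(x, ...) {
  cat(sprintf("Shape cohort: %d subjects, %d bodies\n",
              length(x$subjects), length(x$bodies)))
  for (b in names(x$bodies))
    cat(sprintf("  %s: %d correspondence points\n", b, x$m[[b]]))
  invisible(x)
}

#' Read a cohort from a manifest file
#'
#' The manifest is a CSV with columns `subject_id`, `body`, `path`; each row
#' points to one `.particles` or `.csv` point-cloud file. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param manifest path to the manifest CSV.
#' @param center centre each cloud at the origin (default `TRUE`).
#' @return A [shape_cohort].
#' @export
read_cohort <- function(manifest, center = TRUE) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  need <- c("subject_id", "body", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns subject_id, body, path")
  root <- dirname(manifest)
  clouds <- lapply(seq_len(nrow(df)), function(i) {
    p <- df$path[i]
    if (!file.exists(p)) p <- file.path(root, df$path[i])
    read_particles(p, df$body[i], df$subject_id[i])
  })
  shape_cohort(clouds, center = center)
}

# Stack the requested bodies of a cohort into one data matrix (3m_tot x n)
# plus its block layout. Internal workhorse for model building.
cohort_matrix <- function(cohort, bodies = names(cohort$bodies)) {
  stopifnot(inherits(cohort, "shape_cohort"))
  miss <- setdiff(bodies, names(cohort$bodies))
  if (length(miss)) stop("unknown body label(s): ", paste(miss, collapse = ", "))
  layout <- block_layout(cohort$m[bodies])
  X <- do.call(rbind, cohort$bodies[bodies])
  list(X = X, layout = layout)
}

# Drop subjects (by index) from a cohort; used by the cross-validation loops.
cohort_subset <- function(cohort, keep) {
  structure(list(subjects = cohort$subjects[keep],
                 m = cohort$m,
                 bodies = lapply(cohort$bodies, function(B) B[, keep, drop = FALSE])),
            class = "shape_cohort")
}
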