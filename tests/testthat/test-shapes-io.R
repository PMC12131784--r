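test_that("particles files parse one point per line, preserving order", {
  f <- withr::local_tempfile(fileext = ".particles")
  writeLines(c("0 0 0", "1 2 3"), f)
  pc <- read_particles(f, "scapula", "s01")
  expect_equal(n_points(pc), 2L)
  expect_equal(unclass(pc)[2, ], c(x = 1, y = 2, z = 3))
  expect_equal(attr(pc, "body_label"), "scapula")

  # extra fields beyond x y z are ignored; blank lines skipped
  writeLines(c("", "1 2 3 0.99", "  4 5 6  "), f)
  pc <- read_particles(f)
  expect_equal(n_points(pc), 2L)
  expect_equal(unclass(pc)[1, ], c(x = 1, y = 2, z = 3))
})

test_that("malformed and empty particle files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".particles")
  writeLines("a b c", f)
  expect_error(read_particles(f), "line 1")
  writeLines(c("1 2 3", "4 5"), f)
  expect_error(read_particles(f), "line 2")
  writeLines(character(0), f)
  expect_error(read_particles(f), "empty")
  expect_error(read_particles(file.path(tempdir(), "nope.particles")),
               "not found")
})

test_that("write/read round-trips preserve coordinates to 1e-9", {
  cl <- rand_cloud(10, seed = 42)
  for (ext in c(".particles", ".csv")) {
    f <- withr::local_tempfile(fileext = ext)
    write_particles(cl, f)
    back <- read_particles(f)
    expect_lt(max(abs(unclass(back) - unclass(cl))), 1e-9)
  }
  # line count equals point count
  f <- withr::local_tempfile(fileext = ".particles")
  write_particles(rand_cloud(37, seed = 1), f)
  expect_length(readLines(f), 37L)
  expect_error(write_particles(cl, file.path(tempdir(), "no_dir", "x.particles")),
               "directory")
})

test_that("centering zeroes the centroid, preserves shape, and is idempotent", {
  pc <- point_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(unclass(center_cloud(pc)), rbind(c(-1, 0, 0), c(1, 0, 0)),
               ignore_attr = TRUE)
  cl <- rand_cloud(50, seed = 7, scale = 30)
  cc <- center_cloud(cl)
  expect_lt(sqrt(sum(colMeans(cc)^2)), 1e-9)
  # pairwise distances unchanged (brute-force oracle via dist)
  expect_lt(max(abs(dist(unclass(cl)) - dist(unclass(cc)))), 1e-9)
  expect_equal(unclass(center_cloud(cc)), unclass(cc))
})

test_that("vectorize/devectorize use interleaved layout and are inverse", {
  pc <- point_cloud(rbind(c(1, 2, 3)))
  expect_equal(vectorize(pc), c(1, 2, 3))
  cl <- rand_cloud(17, seed = 3)
  expect_length(vectorize(cl), 51L)
  expect_equal(unclass(devectorize(vectorize(cl))), unclass(cl),
               ignore_attr = TRUE)
  expect_error(devectorize(1:4), "divisible by 3")
})

test_that("multi-body concatenation records a partitioning block layout", {
  cc <- concatenate_bodies(list(a = rnorm(6), b = rnorm(9), c = rnorm(12)))
  expect_length(cc$vector, 27L)
  expect_equal(cc$layout$first, c(1L, 7L, 16L))
  expect_equal(cc$layout$last, c(6L, 15L, 27L))
  # ranges partition the combined index set exactly
  idx <- unlist(lapply(cc$layout$body, block_rows, layout = cc$layout))
  expect_equal(idx, 1:27)
  expect_equal(3L * cc$layout$m, cc$layout$last - cc$layout$first + 1L)

  one <- concatenate_bodies(list(solo = c(1, 2, 3)))
  expect_equal(one$layout$m, 3L %/% 3L)
  expect_equal(one$layout$last, 3L)
  expect_error(concatenate_bodies(list(a = rnorm(4))), "divisible by 3")
})

test_that("cohorts round-trip through a manifest on disk", {
  co <- generate_cohort(small_spec(n = 8, seed = 9))
  d <- withr::local_tempdir()
  read_back <- read_cohort(write_cohort(co, d))
  expect_equal(read_back$subjects, co$subjects)
  for (b in names(co$bodies))
    expect_lt(max(abs(read_back$bodies[[b]] - co$bodies[[b]])), 1e-9)
})

test_that("cohort construction rejects ragged or incomplete input", {
  cl <- list(point_cloud(diag(3), "a", "s1"), point_cloud(diag(3), "a", "s2"),
             point_cloud(diag(3), "b", "s1"))
  expect_error(shape_cohort(cl), "every subject")
  cl2 <- list(point_cloud(diag(3), "a", "s1"),
              point_cloud(matrix(rnorm(12), 4, 3), "a", "s2"))
  expect_error(shape_cohort(cl2), "point count")
})
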