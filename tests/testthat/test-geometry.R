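test_that("PLY round trip preserves vertices and faces exactly", {
  m <- icosphere(2, radius = 23.5, center = c(1.25, -4, 7))
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, path)
  m2 <- read_mesh(path)
  expect_identical(dim(m2$vertices), dim(m$vertices))
  expect_identical(m2$faces, m$faces)
  expect_identical(m2$vertices, m$vertices)
})

test_that("STL and OBJ round trips preserve geometry", {
  m <- ellipsoid_mesh(c(20, 22, 25), subdiv = 1)
  for (ext in c(".stl", ".obj")) {
    path <- withr::local_tempfile(fileext = ext)
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_equal(nrow(m2$faces), nrow(m$faces))
    expect_equal(sort(as.vector(m2$vertices)), sort(as.vector(m$vertices)),
                 tolerance = 1e-7)
  }
})

test_that("degenerate faces are dropped on construction with a message", {
  m <- icosphere(1, 10)
  faces_bad <- rbind(m$faces, c(1L, 1L, 2L))  # zero-area face
  expect_message(m2 <- triangle_mesh(m$vertices, faces_bad),
                 "degenerate")
  expect_equal(nrow(m2$faces), nrow(m$faces))
})

test_that("truncated and malformed mesh files raise format errors", {
  m <- icosphere(1, 10)
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, path)
  lines <- readLines(path)
  writeLines(lines[seq_len(length(lines) - 15)], path)
  expect_error(read_mesh(path), "truncated")
  path2 <- withr::local_tempfile(fileext = ".stl")
  writeLines(c("solid x", "facet", "vertex 0 0 0"), path2)
  expect_error(read_mesh(path2), "STL")
  path3 <- withr::local_tempfile(fileext = ".ply")
  writeLines("not a mesh", path3)
  expect_error(read_mesh(path3), "PLY")
})

test_that("closest_points matches the brute-force all-triangle scan", {
  m <- ellipsoid_mesh(c(18, 21, 26), subdiv = 1)  # 80 faces
  set.seed(42)
  pts <- matrix(runif(100 * 3, -35, 35), ncol = 3)
  got <- closest_points(pts, m)$distance
  want <- vapply(seq_len(nrow(pts)), function(i)
    brute_closest_distance(pts[i, ], m), numeric(1))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("closest point basics: vertices at distance 0, sphere analytic", {
  m <- icosphere(3, 25)
  expect_equal(closest_point_on_mesh(m$vertices[17, ], m)$distance, 0)
  d <- closest_point_on_mesh(c(50, 0, 0), m)$distance
  expect_equal(d, 25, tolerance = 0.1)  # tessellation tolerance
  expect_error(closest_points(matrix(numeric(0), ncol = 3), m), "empty")
})

test_that("procrustes_align recovers a known similarity transform", {
  set.seed(3)
  src <- matrix(rnorm(30), ncol = 3)
  R <- axis_rotation("z", pi / 6) %*% axis_rotation("x", 0.3)
  for (s in c(1, 1.7)) {
    tgt <- s * src %*% t(R) + matrix(c(4, -2, 9), 10, 3, byrow = TRUE)
    tr <- procrustes_align(src, tgt, allow_scale = s != 1)
    expect_equal(tr$rotation, R, tolerance = 1e-9)
    expect_equal(tr$scale, s, tolerance = 1e-9)
    expect_equal(tr$translation, c(4, -2, 9), tolerance = 1e-9)
    expect_lt(tr$rmsd, 1e-9)
    expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  }
  # identity when target equals source
  tr0 <- procrustes_align(src, src)
  expect_equal(tr0$rotation, diag(3), tolerance = 1e-12)
})

test_that("procrustes_align rejects degenerate input", {
  expect_error(procrustes_align(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "3 points")
  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(procrustes_align(line, line + 1), "collinear|degenerate")
})

test_that("procrustes residual beats random similarity transforms", {
  set.seed(8)
  src <- matrix(rnorm(45), ncol = 3)
  tgt <- src %*% t(axis_rotation("y", 0.8)) + 2
  best <- procrustes_align(src, tgt)
  resid <- function(R, t) sqrt(mean(rowSums((src %*% t(R) +
    matrix(t, nrow(src), 3, byrow = TRUE) - tgt)^2)))
  for (i in 1:1000) {
    ax <- c("x", "y", "z")[sample.int(3, 1)]
    R <- axis_rotation(ax, runif(1, -pi, pi))
    expect_gte(resid(R, rnorm(3)), best$rmsd - 1e-12)
  }
})

test_that("annotation CSV and JSON round trips are lossless", {
  set.seed(1)
  lm <- rbind(apex = c(0, 0, -20), base = c(0, 0, 21), posterior = c(0, -19, 1))
  a <- point_annotation("P007", "B", "manual", 1,
                        matrix(rnorm(30, sd = 10), ncol = 3), lm,
                        plane_tags = rep(c("axial", "sagittal"), 5))
  fc <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(a, fc)
  a2 <- read_annotation_csv(fc)
  expect_equal(a2$points, a$points)
  expect_equal(a2$landmarks, a$landmarks)
  expect_identical(a2$plane_tags, a$plane_tags)
  expect_identical(a2$session, 1L)
  fj <- withr::local_tempfile(fileext = ".json")
  write_annotation_json(a, fj)
  a3 <- read_annotation_json(fj)
  expect_equal(a3$points, a$points)
  expect_equal(a3$landmarks, a$landmarks)
})

test_that("annotation files missing a landmark are rejected", {
  a <- surface_annotation(icosphere(2, 20), n = 10)
  fc <- withr::local_tempfile(fileext = ".csv")
  write_annotation_csv(a, fc)
  df <- utils::read.csv(fc)
  utils::write.csv(df[df$label != "apex", ], fc, row.names = FALSE)
  expect_error(read_annotation_csv(fc), "apex")
})

test_that("unknown JSON keys are ignored with a message", {
  a <- surface_annotation(icosphere(2, 20), n = 5)
  fj <- withr::local_tempfile(fileext = ".json")
  write_annotation_json(a, fj)
  obj <- jsonlite::read_json(fj)
  obj$scanner_model <- "probe-x1"
  jsonlite::write_json(obj, fj, auto_unbox = TRUE, digits = NA)
  expect_message(a2 <- read_annotation_json(fj), "scanner_model")
  expect_equal(nrow(a2$points), nrow(a$points))
})

test_that("watertightness detection flags open meshes", {
  m <- icosphere(1, 10)
  expect_true(as.logical(is_watertight(m)))
  open <- m
  open$faces <- open$faces[-1, , drop = FALSE]
  expect_false(as.logical(is_watertight(open)))
  expect_warning(
    read_mesh(write_mesh(open, withr::local_tempfile(fileext = ".ply"))),
    "watertight")
})
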