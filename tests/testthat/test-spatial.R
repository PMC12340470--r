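test_that("registration maps mean-shape samples back onto themselves and
           absorbs rigid motion", {
  ssm <- toy_ssm()
  ann <- surface_annotation(ssm$mean_shape, n = 80, seed = 2)
  reg <- register_annotation_to_reference(ann, ssm)
  expect_lt(max(sqrt(rowSums((reg$mapped - ann$points)^2))), 0.2)
  tr <- list(rotation = axis_rotation("z", 0.9), translation = c(7, -4, 2),
             scale = 1)
  ann_r <- point_annotation("P", "E", "manual", 0,
                            apply_transform(ann$points, tr),
                            apply_transform(ann$landmarks, tr))
  reg_r <- register_annotation_to_reference(ann_r, ssm)
  expect_lt(max(sqrt(rowSums((reg_r$mapped - reg$mapped)^2))), 0.3)
})

test_that("registration preserves the scatter of a tight cluster", {
  ssm <- toy_ssm()
  ref <- ssm$mean_shape
  anchor <- ref$vertices[10, ]
  set.seed(14)
  cluster <- matrix(rep(anchor, 30), ncol = 3, byrow = TRUE) +
    matrix(rnorm(90, 0, 1.5), ncol = 3)
  cp <- closest_points(cluster, ref)
  ann <- point_annotation("P", "E", "manual", 0, cp$closest,
                          mesh_landmarks(ref))
  reg <- register_annotation_to_reference(ann, ssm)
  scatter0 <- mean(dist(cp$closest))
  scatter1 <- mean(dist(reg$mapped))
  expect_lt(abs(scatter1 - scatter0) / scatter0, 0.2)
})

test_that("density map integrates to the point count and is near-uniform
           for uniform sampling", {
  ssm <- toy_ssm()
  ref <- ssm$mean_shape
  set.seed(15)
  pts <- sample_surface_points(ref, 5000)
  dm <- surface_density_map(ref, pts, bandwidth_mm = 5)
  va <- vertex_areas(ref)
  expect_equal(sum(dm$per_vertex_value * va), 5000, tolerance = 0.02 * 5000)
  cv <- sd(dm$per_vertex_value) / mean(dm$per_vertex_value)
  expect_lt(cv, 0.15)
  # doubling the points doubles the integral
  dm2 <- surface_density_map(ref, rbind(pts, pts), bandwidth_mm = 5)
  expect_equal(sum(dm2$per_vertex_value * va) /
                 sum(dm$per_vertex_value * va), 2, tolerance = 1e-6)
})

test_that("density is maximal at a pole when all points sit there", {
  ssm <- toy_ssm()
  ref <- ssm$mean_shape
  lm <- mesh_landmarks(ref)
  pts <- matrix(rep(lm["apex", ], 50), ncol = 3, byrow = TRUE)
  dm <- surface_density_map(ref, pts, bandwidth_mm = 5)
  apex_vertex <- which.min(ref$vertices[, 3])
  expect_equal(which.max(dm$per_vertex_value), apex_vertex)
})

test_that("ASD map reproduces constant and two-level fields", {
  ssm <- toy_ssm()
  ref <- ssm$mean_shape
  set.seed(16)
  pts <- sample_surface_points(ref, 2000)
  m_const <- surface_asd_map(ref, pts, rep(1.7, 2000), bandwidth_mm = 5)
  expect_equal(range(m_const$per_vertex_value, na.rm = TRUE), c(1.7, 1.7),
               tolerance = 1e-9)
  ci <- prosegvar:::.cap_info(ref)
  apex_pts <- sqrt(rowSums(sweep(pts, 2, ci$apex)^2)) <= ci$r_apex
  vals <- ifelse(apex_pts, 2, 1)
  m2 <- surface_asd_map(ref, pts, vals, bandwidth_mm = 3)
  apex_vertex <- which.min(ref$vertices[, 3])
  far_vertex <- which.max(ref$vertices[, 3])
  expect_gt(m2$per_vertex_value[apex_vertex], 1.7)
  expect_lt(m2$per_vertex_value[far_vertex], 1.2)
  expect_error(surface_asd_map(ref, pts, vals[-1]), "paired")
})

test_that("global mean ASD is consistent with the density-weighted map
           decomposition", {
  ssm <- toy_ssm()
  ref <- ssm$mean_shape
  set.seed(18)
  pts <- sample_surface_points(ref, 3000)
  vals <- runif(3000, 0.5, 2)
  dm <- surface_density_map(ref, pts, 5)
  am <- surface_asd_map(ref, pts, vals, 5)
  va <- vertex_areas(ref)
  integral <- sum(dm$per_vertex_value * am$per_vertex_value * va,
                  na.rm = TRUE)
  expect_equal(integral / 3000, mean(vals), tolerance = 0.03)
})

test_that("sparsity-driven cohorts show the inverse density/ASD
           relationship", {
  ssm <- toy_ssm()
  ref <- ssm$mean_shape
  ci <- prosegvar:::.cap_info(ref)
  set.seed(19)
  cand <- sample_surface_points(ref, 4000)
  in_cap <- prosegvar:::.in_cap(cand, ci)
  keep <- runif(4000) < ifelse(in_cap, 0.3, 1)
  pts <- cand[keep, , drop = FALSE]
  # disagreement is larger where annotation is sparse
  vals <- ifelse(prosegvar:::.in_cap(pts, ci), 2.0, 1.0) +
    rnorm(nrow(pts), 0, 0.2)
  dm <- surface_density_map(ref, pts, 5)
  am <- surface_asd_map(ref, pts, vals, 5)
  ok <- !is.na(am$per_vertex_value)
  rho <- cor(dm$per_vertex_value[ok], am$per_vertex_value[ok],
             method = "spearman")
  expect_lt(rho, -0.3)
})

test_that("pole caps cover the requested area fraction", {
  ssm <- toy_ssm()
  ref <- ssm$mean_shape
  caps <- pole_caps(ref, 0.25)
  va <- vertex_areas(ref)
  expect_equal(sum(va[caps$apex]) / sum(va), 0.25, tolerance = 0.05)
  expect_equal(sum(va[caps$base]) / sum(va), 0.25, tolerance = 0.05)
})

test_that("surface maps export as PLY with a quality property and CSV", {
  ssm <- toy_ssm()
  ref <- ssm$mean_shape
  dm <- surface_density_map(ref, sample_surface_points(ref, 100), 5)
  ply <- withr::local_tempfile(fileext = ".ply")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_surface_map(dm, ply, csv)
  expect_true(any(grepl("quality", readLines(ply, n = 12))))
  got <- utils::read.csv(csv)
  expect_equal(nrow(got), nrow(ref$vertices))
})
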