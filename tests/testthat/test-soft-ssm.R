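test_that("large regularization weight pins the fit to the strict
           subspace solution", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 11)
  ann <- surface_annotation(truth, n = 150, seed = 3)
  soft <- fit_soft_ssm(ssm, ann, soft_fit_config(regularization_weight = 1e6))
  strict <- attr(soft, "strict_fit")$mesh
  expect_lt(asd_mesh_to_mesh(soft, strict), 0.02)
})

test_that("small weight follows out-of-subspace truth more closely than
           the strict fit", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 11)
  ann <- surface_annotation(truth, n = 300, seed = 4)
  soft <- fit_soft_ssm(ssm, ann,
                       soft_fit_config(regularization_weight = 0.002))
  resid_soft <- attr(soft, "mean_residual_mm")
  resid_strict <- mean(closest_points(annotation_points(ann),
                                      attr(soft, "strict_fit")$mesh)$distance)
  expect_lt(resid_soft, 0.2)
  expect_lt(resid_soft, resid_strict)
})

test_that("soft fit is deterministic and keeps the model topology", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 23)
  ann <- surface_annotation(truth, n = 100, seed = 5)
  a <- fit_soft_ssm(ssm, ann)
  b <- fit_soft_ssm(ssm, ann)
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, ssm$mean_shape$faces)
})

test_that("point residual is monotone in the regularization weight", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 37)
  ann <- surface_annotation(truth, n = 200, seed = 6)
  resids <- vapply(c(10, 1, 0.1, 0.01, 0.001), function(w)
    attr(fit_soft_ssm(ssm, ann, soft_fit_config(regularization_weight = w)),
         "mean_residual_mm"), numeric(1))
  expect_true(all(diff(resids) <= 1e-6))
})

test_that("deformation objective trace is non-increasing", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 41)
  ann <- surface_annotation(truth, n = 120, seed = 7)
  soft <- fit_soft_ssm(ssm, ann)
  tr <- attr(soft, "objective_trace")
  expect_true(all(diff(tr) <= 1e-6))
})

test_that("refining with a point already on the surface changes nothing", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 29)
  ann <- surface_annotation(truth, n = 100, seed = 8)
  soft <- fit_soft_ssm(ssm, ann)
  on_surf <- closest_points(matrix(c(0, 0, 0), ncol = 3), soft)$closest
  refined <- incremental_refine(soft, ssm, on_surf,
                                accumulated = annotation_points(ann))
  expect_lt(asd_mesh_to_mesh(refined, soft), 0.05)
})

test_that("refinement with landmarks matches a fresh batch fit exactly", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 47)
  set.seed(10)
  pts <- sample_surface_points(truth, 30)
  lm <- mesh_landmarks(truth)
  batch <- fit_soft_ssm(ssm, point_annotation("P", "E", "semi_auto", 0,
                                              pts, lm))
  start <- fit_soft_ssm(ssm, point_annotation("P", "E", "semi_auto", 0,
                                              matrix(numeric(0), ncol = 3),
                                              lm))
  ref <- incremental_refine(start, ssm, pts, accumulated = NULL,
                            landmarks = lm)
  expect_equal(ref$vertices, batch$vertices, tolerance = 1e-12)
})

test_that("a far-off correction point moves the surface locally only", {
  ssm <- toy_ssm()
  base <- sample_ssm(ssm, numeric(length(ssm$eigenvalues)))
  lm <- mesh_landmarks(base)
  # pull a point 5 mm outside near the +x equator
  anchor <- closest_points(matrix(c(50, 0, 0), ncol = 3), base)$closest
  dir <- anchor / sqrt(sum(anchor^2))
  target <- anchor + 5 * dir
  refined <- incremental_refine(base, ssm, target)
  moved <- sqrt(rowSums((refined$vertices - base$vertices)^2))
  near <- sqrt(rowSums(sweep(base$vertices, 2, drop(anchor))^2)) < 8
  far_hemisphere <- base$vertices[, 1] < 0
  expect_gt(max(moved[near]), 1)  # local surface moves toward the point
  # far hemisphere essentially untouched: an order of magnitude below
  # the pull, bounded by the lattice regularizer's decay
  expect_lt(mean(moved[far_hemisphere]), 0.3)
  expect_lt(mean(moved[far_hemisphere]), 0.1 * max(moved[near]))
})

test_that("sequential batches and one batch fit agree within tolerance", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 31)
  set.seed(9)
  pts <- sample_surface_points(truth, 40)
  lm <- mesh_landmarks(truth)
  ann_all <- point_annotation("P", "E", "semi_auto", 0, pts, lm)
  batch <- fit_soft_ssm(ssm, ann_all)
  ann0 <- point_annotation("P", "E", "semi_auto", 0,
                           matrix(numeric(0), ncol = 3), lm)
  seq_mesh <- fit_soft_ssm(ssm, ann0)
  acc <- NULL
  for (i in seq(1, 40, by = 10)) {
    newp <- pts[i:min(i + 9, 40), , drop = FALSE]
    seq_mesh <- incremental_refine(seq_mesh, ssm, newp, accumulated = acc,
                                   landmarks = lm)
    acc <- rbind(acc, newp)
  }
  expect_lt(asd_mesh_to_mesh(seq_mesh, batch), 0.3)
})

test_that("config validation rejects impossible settings", {
  expect_error(soft_fit_config(control_grid_spacing = 0), "spacing")
  expect_error(soft_fit_config(regularization_weight = -1), ">= 0")
})
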