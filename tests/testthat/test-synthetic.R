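test_that("toy model building is deterministic in the seed", {
  a <- build_toy_ssm(seed = 3, n_train = 12)
  b <- build_toy_ssm(seed = 3, n_train = 12)
  expect_identical(a$mean_shape$vertices, b$mean_shape$vertices)
  expect_identical(a$eigenvalues, b$eigenvalues)
  c <- build_toy_ssm(seed = 4, n_train = 12)
  expect_false(identical(a$mean_shape$vertices, c$mean_shape$vertices))
})

test_that("sampled training shapes have prostate-plausible volumes", {
  ssm <- toy_ssm()
  set.seed(61)
  vols <- replicate(200, {
    ev <- ssm$eigenvalues
    b <- pmin(pmax(rnorm(length(ev), 0, sqrt(ev)), -3 * sqrt(ev)),
              3 * sqrt(ev))
    mesh_volume(sample_ssm(ssm, b)) / 1000
  })
  expect_true(all(vols > 15 & vols < 90))
})

test_that("zero perturbation amplitude gives a low-rank ellipsoid model", {
  ssm0 <- build_toy_ssm(seed = 5, n_train = 20, perturb_amplitude = 0,
                        variance_retained = 0.999)
  expect_lte(length(ssm0$eigenvalues), 6)
})

test_that("patients without out-of-subspace detail are fit exactly by the
           strict model; with detail the residual is substantial", {
  ssm <- toy_ssm()
  clean <- simulate_patient(ssm, seed = 21, oos_amplitude_mm = 0)
  ann_c <- surface_annotation(clean, n = 250, seed = 1)
  fit_c <- fit_ssm_to_points(ssm, ann_c, max_iter = 40, tol_mm = 1e-6)
  expect_lt(tail(fit_c$objective_trace, 1), 0.02)
  detailed <- simulate_patient(ssm, seed = 21, oos_amplitude_mm = 1)
  ann_d <- surface_annotation(detailed, n = 250, seed = 1)
  fit_d <- fit_ssm_to_points(ssm, ann_d, max_iter = 40, tol_mm = 1e-6)
  expect_gt(tail(fit_d$objective_trace, 1), 0.3)
  expect_false(identical(simulate_patient(ssm, 1)$vertices,
                         simulate_patient(ssm, 2)$vertices))
})

test_that("noise-free annotations lie on the truth surface", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 33)
  cfg <- cohort_config(point_noise_sd_mm = 0, expert_bias_sd_mm = 0,
                       pole_sparsity = 0, manual_points_range = c(80, 120))
  ex <- expert_profile("A", cfg, 7)
  ann <- simulate_manual_annotation(truth, ex, cfg, seed = 9)
  expect_lt(asd_points_to_mesh(ann$points, truth), 1e-6)
})

test_that("point jitter produces the half-normal distance expectation", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 33)
  cfg <- cohort_config(point_noise_sd_mm = 1, expert_bias_sd_mm = 0,
                       pole_sparsity = 0, cap_noise_factor = 1,
                       manual_points_range = c(400, 500))
  ex <- expert_profile("A", cfg, 7)
  ann <- simulate_manual_annotation(truth, ex, cfg, seed = 10)
  # normal-direction component of an iid 3D jitter: E|N(0,1)| ~ 0.80
  expect_equal(asd_points_to_mesh(ann$points, truth), 0.80,
               tolerance = 0.12)
})

test_that("pole sparsity starves the apex cap of points", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 33)
  cfg <- cohort_config(point_noise_sd_mm = 0, expert_bias_sd_mm = 0,
                       pole_sparsity = 0.7,
                       manual_points_range = c(400, 500))
  ex <- expert_profile("A", cfg, 7)
  ann <- simulate_manual_annotation(truth, ex, cfg, seed = 11)
  ci <- prosegvar:::.cap_info(truth)
  share_sparse <- mean(prosegvar:::.in_cap(ann$points, ci))
  cfg0 <- cohort_config(point_noise_sd_mm = 0, expert_bias_sd_mm = 0,
                        pole_sparsity = 0,
                        manual_points_range = c(400, 500))
  ann0 <- simulate_manual_annotation(truth, ex, cfg0, seed = 11)
  share_dense <- mean(prosegvar:::.in_cap(ann0$points, ci))
  # strong depletion relative to the unthinned sampling of the same slices
  expect_lt(share_sparse, 0.55 * share_dense)
  expect_lt(share_sparse, 0.30)
})

test_that("manual point counts respect the configured envelope", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 35)
  cfg <- cohort_config(manual_points_range = c(81, 573))
  ex <- expert_profile("B", cfg, 8)
  for (s in 1:3) {
    ann <- simulate_manual_annotation(truth, ex, cfg, seed = s)
    expect_gte(nrow(ann$points), 81)
    expect_lte(nrow(ann$points), 573)
  }
})

test_that("semi-automatic sessions are deterministic and improve on the
           landmark-only prior", {
  ssm <- toy_ssm()
  truth <- simulate_patient(ssm, seed = 43)
  cfg <- cohort_config(point_noise_sd_mm = 0, expert_bias_sd_mm = 0,
                       semi_auto_points_range = c(40, 40))
  ex <- expert_profile("C", cfg, 9)
  rec1 <- simulate_semiauto_session(truth, ssm, ex, cfg, seed = 12)
  rec2 <- simulate_semiauto_session(truth, ssm, ex, cfg, seed = 12)
  expect_identical(rec1$mesh$vertices, rec2$mesh$vertices)
  # landmark-only prior fit (zero corrections)
  lm <- prosegvar:::with_seed(12, prosegvar:::.noisy_landmarks(truth, ex, cfg))
  ann0 <- point_annotation("P", "C", "semi_auto", 0,
                           matrix(numeric(0), ncol = 3), lm)
  prior <- fit_soft_ssm(ssm, ann0, cfg$soft_cfg)
  expect_lt(asd_mesh_to_mesh(rec1$mesh, truth),
            asd_mesh_to_mesh(prior, truth))
})

test_that("segmentation records enforce provenance/mesh consistency", {
  ssm <- toy_ssm()
  ann <- surface_annotation(ssm$mean_shape, n = 10)
  expect_error(segmentation_record(ann, NULL, "semi_auto_soft_SSM"),
               "requires a mesh")
  expect_error(segmentation_record(ann, ssm$mean_shape, "manual_points"),
               "no mesh")
  rec <- segmentation_record(ann, NULL, "manual_points")
  expect_s3_class(rec, "segmentation_record")
})

test_that("cohort record counts match the design arithmetic", {
  cfg <- tiny_cohort_config()
  design <- cohort_design(cfg)
  coh <- tiny_cohort()
  mf <- coh$manifest
  expect_equal(sum(mf$method == "manual" & mf$session == 0), design$manual)
  expect_equal(sum(mf$method == "manual" & mf$session == 1),
               design$manual_bis)
  expect_equal(sum(mf$method == "semi_auto" & mf$session == 0),
               design$semi_auto)
  expect_equal(sum(mf$method == "semi_auto" & mf$session == 1),
               design$semi_auto_bis)
  expect_equal(nrow(mf), design$total)
})

test_that("the full-scale design arithmetic matches hand counts", {
  cfg <- cohort_config(n_patients = 100, n_experts = 4,
                       shared_subset_size = 12, bis_subset_size = 5,
                       max_manual_per_expert = 25)
  d <- cohort_design(cfg)
  # 88 non-shared patients dealt round-robin to 4 experts = 22 each;
  # manual capped at 25 per expert (12 shared + 13 extras)
  expect_equal(d$manual, 4 * 25)
  expect_equal(d$manual_bis, 4 * 5)
  expect_equal(d$semi_auto, 4 * 12 + 88)
  expect_equal(d$semi_auto_bis, 2 * 5)
})

test_that("same seed gives an identical manifest hash, different seed
           does not", {
  cfg <- cohort_config(n_patients = 3, n_experts = 2, seed = 9,
                       shared_subset_size = 2, bis_subset_size = 1,
                       manual_points_range = c(40, 60),
                       semi_auto_points_range = c(8, 10))
  h1 <- cohort_manifest_hash(generate_cohort(cfg, ssm = toy_ssm()))
  h2 <- cohort_manifest_hash(generate_cohort(cfg, ssm = toy_ssm()))
  expect_identical(h1, h2)
  cfg2 <- cohort_config(n_patients = 3, n_experts = 2, seed = 10,
                        shared_subset_size = 2, bis_subset_size = 1,
                        manual_points_range = c(40, 60),
                        semi_auto_points_range = c(8, 10))
  expect_false(identical(h1,
    cohort_manifest_hash(generate_cohort(cfg2, ssm = toy_ssm()))))
})

test_that("config validation catches inconsistent settings", {
  expect_error(cohort_config(shared_subset_size = 10, n_patients = 5),
               "exceed")
  expect_error(cohort_config(pole_sparsity = 1), "pole_sparsity")
  expect_error(cohort_config(manual_points_range = c(100, 50)), "ordered")
})
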