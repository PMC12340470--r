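#' Cohort simulation configuration
#'
#' Defaults emulate the study design this package analyses: four experts
#' from whom each prostate receives manual point segmentations (a shared
#' subset annotated by everyone, a smaller subset annotated twice for
#' intra-observer analysis) and semi-automatic sessions, with manual point
#' counts spanning the observed 81-573 per-session envelope and
#' semi-automatic counts the 31-105 envelope. Noise parameters (per-point
#' jitter, smooth per-expert bias, apex/base sparsity, axial slice
#' quantization) are the minimal mechanisms behind the variability
#' structure the analysis measures; their defaults are discussed in the
#' methods vignette.
#'
#' @param n_patients number of prostates in the cohort.
#' @param n_experts number of simulated experts.
#' @param seed master seed; every derived random draw is a deterministic
#'   function of it.
#' @param manual_points_range min/max manual points per session.
#' @param semi_auto_points_range min/max total semi-automatic points
#'   (landmarks + corrections) per session.
#' @param point_noise_sd_mm SD of the iid Gaussian jitter on every placed
#'   point (mm).
#' @param expert_bias_sd_mm amplitude of each expert's smooth systematic
#'   radial bias field (mm).
#' @param pole_sparsity fractional reduction of sampling density inside
#'   the apex/base caps, in [0, 1); applies to manual contour points and
#'   to where semi-automatic correction points are placed.
#' @param cap_noise_factor multiplier on the point jitter inside the
#'   apex/base caps (these regions are the hardest to visualize on the
#'   axial slices, so clicks there are noisier).
#' @param slice_spacing_mm axial plane spacing for manual points (mm).
#' @param shared_subset_size patients annotated by all experts.
#' @param bis_subset_size patients re-annotated ("bis" sessions).
#' @param max_manual_per_expert cap on manual sessions per expert.
#' @param n_semiauto_bis_experts how many experts repeat semi-automatic
#'   sessions on the bis subset.
#' @param soft_cfg [soft_fit_config()] used by the semi-automatic
#'   simulator.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 100, n_experts = 4, seed = 1,
                          manual_points_range = c(81, 573),
                          semi_auto_points_range = c(31, 105),
                          point_noise_sd_mm = 0.6,
                          expert_bias_sd_mm = 0.5,
                          pole_sparsity = 0.6,
                          cap_noise_factor = 2.0,
                          slice_spacing_mm = 2.0,
                          shared_subset_size = 12,
                          bis_subset_size = 5,
                          max_manual_per_expert = 25,
                          n_semiauto_bis_experts = 2,
                          soft_cfg = soft_fit_config()) {
  stopifnot(length(manual_points_range) == 2,
            length(semi_auto_points_range) == 2)
  if (any(manual_points_range <= 0) || diff(manual_points_range) < 0 ||
      any(semi_auto_points_range <= 0) || diff(semi_auto_points_range) < 0)
    stop("point-count ranges must be positive and ordered")
  if (semi_auto_points_range[1] < 4)
    stop("semi-automatic sessions need at least 4 points (3 landmarks + 1)")
  if (pole_sparsity < 0 || pole_sparsity >= 1)
    stop("pole_sparsity must be in [0, 1)")
  if (shared_subset_size > n_patients)
    stop("shared_subset_size cannot exceed n_patients")
  if (bis_subset_size > shared_subset_size)
    stop("bis subset must lie inside the shared subset")
  if (max_manual_per_expert < shared_subset_size)
    stop("max_manual_per_expert must cover the shared subset")
  if (n_semiauto_bis_experts > n_experts)
    stop("n_semiauto_bis_experts cannot exceed n_experts")
  structure(list(n_patients = as.integer(n_patients),
                 n_experts = as.integer(n_experts), seed = as.integer(seed),
                 manual_points_range = as.integer(manual_points_range),
                 semi_auto_points_range = as.integer(semi_auto_points_range),
                 point_noise_sd_mm = point_noise_sd_mm,
                 expert_bias_sd_mm = expert_bias_sd_mm,
                 pole_sparsity = pole_sparsity,
                 cap_noise_factor = cap_noise_factor,
                 slice_spacing_mm = slice_spacing_mm,
                 shared_subset_size = as.integer(shared_subset_size),
                 bis_subset_size = as.integer(bis_subset_size),
                 max_manual_per_expert = as.integer(max_manual_per_expert),
                 n_semiauto_bis_experts = as.integer(n_semiauto_bis_experts),
                 soft_cfg = soft_cfg),
            class = "cohort_config")
}

# evaluate code with a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + as.double(k) * 104729) %% 2147483562) + 1L
}

# Low-order ("band-limited") angular basis: restrictions of harmonic
# polynomials of degree 1-3 to the unit sphere, columns normalized to unit
# RMS over a dense reference sampling so random coefficient vectors of
# norm A produce radial fields of RMS about A.
.harmonic_cache <- new.env(parent = emptyenv())

.harmonic_basis_raw <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(x, y, z,
        x * y, x * z, y * z, x^2 - y^2, 3 * z^2 - 1,
        x * y * z, z * (x^2 - y^2), x * (x^2 - 3 * y^2), z * (5 * z^2 - 3))
}

.harmonic_basis <- function(dirs) {
  norms <- .harmonic_cache$norms
  if (is.null(norms)) {
    ref <- icosphere(3, radius = 1)$vertices
    norms <- sqrt(colMeans(.harmonic_basis_raw(ref)^2))
    .harmonic_cache$norms <- norms
  }
  sweep(.harmonic_basis_raw(dirs), 2, norms, "/")
}

# random smooth radial field coefficients of RMS amplitude `amplitude`
# (basis columns have unit RMS and are near-orthogonal on the sphere)
.field_coeffs <- function(amplitude) {
  b <- stats::rnorm(12)
  if (amplitude == 0) return(numeric(12))
  b / sqrt(sum(b^2)) * amplitude
}

.eval_field <- function(coeffs, dirs) {
  drop(.harmonic_basis(dirs) %*% coeffs)
}

# Localized Gaussian-bump radial field: anatomical surface detail that no
# low-order harmonic combination (hence no model built from such shapes)
# can represent, used for the deliberate out-of-subspace component of
# simulated patients.
.bump_coeffs <- function(amplitude, n_bumps = 8, width_rad = 0.2) {
  centers <- matrix(stats::rnorm(3 * n_bumps), ncol = 3)
  centers <- centers / sqrt(rowSums(centers^2))
  amps <- stats::rnorm(n_bumps)
  bf <- list(centers = centers, amps = amps, width_rad = width_rad)
  if (amplitude == 0) { bf$amps <- rep(0, n_bumps); return(bf) }
  ref <- icosphere(2, radius = 1)$vertices
  rms <- sqrt(mean(.eval_bump_field(bf, ref)^2))
  bf$amps <- amps * amplitude / max(rms, 1e-12)
  bf
}

.eval_bump_field <- function(bf, dirs) {
  cosang <- pmin(pmax(dirs %*% t(bf$centers), -1), 1)
  ang <- acos(cosang)
  drop(exp(-ang^2 / (2 * bf$width_rad^2)) %*% bf$amps)
}

#' Toy statistical shape model for synthetic cohorts
#'
#' Training shapes are triaxial ellipsoids (overall size 18.5-24.5 mm with
#' per-axis anisotropy 0.92-1.08, giving semi-axes within 15-30 mm and
#' prostate-plausible volumes) carrying smooth low-order angular radial
#' perturbations (harmonic-polynomial bands of degree <= 3, RMS amplitude
#' up to `perturb_amplitude` mm) on a shared icosphere topology. A model
#' built from them stands in for one trained on clinical meshes.
#'
#' @param seed RNG seed; the same seed yields a bit-identical model.
#' @param n_train number of training shapes (>= 10).
#' @param subdiv icosphere subdivision (3 gives 642 vertices).
#' @param perturb_amplitude maximum RMS radial perturbation (mm); 0 gives
#'   pure ellipsoids.
#' @param variance_retained passed to [build_ssm()].
#' @return a `statistical_shape_model`.
#' @export
build_toy_ssm <- function(seed = 1, n_train = 50, subdiv = 3,
                          perturb_amplitude = 3, variance_retained = 0.95) {
  if (n_train < 10) stop("need at least 10 training shapes")
  with_seed(seed, {
    template <- icosphere(subdiv, radius = 1)
    dirs <- template$vertices
    training <- lapply(seq_len(n_train), function(i) {
      s <- stats::runif(1, 18.5, 24.5)
      axes <- s * stats::runif(3, 0.92, 1.08)
      r_ell <- 1 / sqrt((dirs[, 1] / axes[1])^2 + (dirs[, 2] / axes[2])^2 +
                        (dirs[, 3] / axes[3])^2)
      amp <- stats::runif(1, 0, perturb_amplitude)
      field <- if (amp > 0) .eval_field(.field_coeffs(amp), dirs) else 0
      triangle_mesh(dirs * (r_ell + field), template$faces,
                    topology_id = template$topology_id)
    })
    build_ssm(training, variance_retained = variance_retained)
  })
}

#' Simulate a ground-truth prostate surface
#'
#' Draws mode loadings from the model's own distribution (Normal(0,
#' eigenvalue), truncated at 3 standard deviations) and adds a small
#' out-of-subspace radial perturbation. The perturbation is deliberate:
#' real glands are not perfectly captured by any finite shape model, and
#' it is this residual detail that separates the strict-subspace
#' reconstruction from the deformable one downstream.
#'
#' @param ssm a `statistical_shape_model`.
#' @param seed RNG seed.
#' @param oos_amplitude_mm RMS amplitude of the out-of-subspace radial
#'   field (mm); 0 gives an exactly in-subspace shape.
#' @return a `triangle_mesh` on the model topology.
#' @export
simulate_patient <- function(ssm, seed, oos_amplitude_mm = 1) {
  .assert_ssm(ssm)
  with_seed(seed, {
    ev <- ssm$eigenvalues
    b <- stats::rnorm(length(ev), 0, sqrt(ev))
    b <- .clamp_coeffs(b, ev)
    m <- sample_ssm(ssm, b)
    if (oos_amplitude_mm > 0) {
      ctr <- colMeans(m$vertices)
      rel <- sweep(m$vertices, 2, ctr)
      rad <- sqrt(rowSums(rel^2))
      dirs <- rel / rad
      field <- .eval_bump_field(.bump_coeffs(oos_amplitude_mm), dirs)
      m$vertices <- sweep(dirs * (rad + field), 2, ctr, "+")
    }
    m
  })
}

#' Simulated expert profile
#'
#' An expert is characterized by a smooth systematic radial bias field
#' (the mechanism that makes inter-expert variability exceed intra-expert
#' variability) drawn once per expert.
#' @param expert_id identifier.
#' @param cfg a `cohort_config`.
#' @param seed RNG seed for the bias draw.
#' @return list with `id`, `bias_coeffs`.
#' @export
expert_profile <- function(expert_id, cfg, seed) {
  with_seed(seed, {
    list(id = as.character(expert_id),
         bias_coeffs = .field_coeffs(cfg$expert_bias_sd_mm))
  })
}

# expert bias displacement (radial) at points, relative to mesh centroid
.expert_bias <- function(points, centroid, expert) {
  rel <- sweep(points, 2, centroid)
  rad <- sqrt(rowSums(rel^2))
  rad[rad == 0] <- 1
  dirs <- rel / rad
  dirs * .eval_field(expert$bias_coeffs, dirs)
}

# intersection points of mesh edges with the plane {coord[axis] == value}
.plane_contour <- function(m, axis, value) {
  V <- m$vertices; F <- m$faces
  out <- vector("list", 3)
  pairs <- list(c(1, 2), c(2, 3), c(3, 1))
  for (e in 1:3) {
    i <- F[, pairs[[e]][1]]; j <- F[, pairs[[e]][2]]
    a <- V[i, axis] - value; b <- V[j, axis] - value
    cross <- a * b < 0
    if (!any(cross)) next
    t <- a[cross] / (a[cross] - b[cross])
    out[[e]] <- V[i[cross], , drop = FALSE] +
      t * (V[j[cross], , drop = FALSE] - V[i[cross], , drop = FALSE])
  }
  pts <- do.call(rbind, out)
  if (is.null(pts)) return(matrix(numeric(0), ncol = 3))
  unique(round(pts, 9))
}

# apex/base cap membership test for arbitrary surface points, using the
# cap radii implied by the 25%-area vertex caps
.cap_info <- function(truth, frac = 0.25) {
  caps <- pole_caps(truth, frac)
  lm0 <- mesh_landmarks(truth)
  r_of <- function(idx, pole)
    max(sqrt(rowSums(sweep(truth$vertices[idx, , drop = FALSE], 2, pole)^2)))
  list(apex = lm0["apex", ], base = lm0["base", ],
       r_apex = r_of(caps$apex, lm0["apex", ]),
       r_base = r_of(caps$base, lm0["base", ]))
}

.in_cap <- function(points, ci) {
  sqrt(rowSums(sweep(points, 2, ci$apex)^2)) <= ci$r_apex |
    sqrt(rowSums(sweep(points, 2, ci$base)^2)) <= ci$r_base
}

# noisy protocol landmarks of a truth surface under an expert's hand;
# apex and base sit in the poorly visualized polar regions, so their
# placement shares the cap noise inflation
.noisy_landmarks <- function(truth, expert, cfg) {
  lm <- mesh_landmarks(truth)
  ctr <- colMeans(truth$vertices)
  sd_lm <- cfg$point_noise_sd_mm *
    c(cfg$cap_noise_factor, cfg$cap_noise_factor, 1)
  lm + matrix(stats::rnorm(9, 0, sd_lm), 3) +
    .expert_bias(lm, ctr, expert)
}

#' Simulate one manual point-placement session
#'
#' Emulates the manual protocol: three reference landmarks (apex, base,
#' posterior) placed at the surface extremes, contour points on one medial
#' coronal and one medial sagittal slice, and all remaining points on
#' axial slices at `slice_spacing_mm` (the slice quantization of the
#' acquisition). Sampling density is reduced by `pole_sparsity` inside the
#' apex/base caps, and every placed point is displaced by iid Gaussian
#' jitter plus the expert's smooth systematic bias field.
#'
#' @param truth ground-truth `triangle_mesh`.
#' @param expert an [expert_profile()].
#' @param cfg a `cohort_config`.
#' @param seed RNG seed.
#' @param session repeat index (0 or 1).
#' @param patient_id,method record identifiers.
#' @return a `point_annotation`.
#' @export
simulate_manual_annotation <- function(truth, expert, cfg, seed,
                                       session = 0, patient_id = "P",
                                       method = "manual") {
  .assert_mesh(truth)
  with_seed(seed, {
    ctr <- colMeans(truth$vertices)
    lm <- .noisy_landmarks(truth, expert, cfg)
    zr <- range(truth$vertices[, 3])
    zs <- seq(zr[1] + cfg$slice_spacing_mm / 2, zr[2],
              by = cfg$slice_spacing_mm)
    cand <- list(); tags <- list()
    for (z in zs) {
      p <- .plane_contour(truth, 3, z)
      if (nrow(p)) { cand[[length(cand) + 1]] <- p
                     tags[[length(tags) + 1]] <- rep("axial", nrow(p)) }
    }
    for (sl in list(list(1, "sagittal"), list(2, "coronal"))) {
      p <- .plane_contour(truth, sl[[1]], ctr[sl[[1]]])
      if (nrow(p)) { cand[[length(cand) + 1]] <- p
                     tags[[length(tags) + 1]] <- rep(sl[[2]], nrow(p)) }
    }
    cand <- do.call(rbind, cand); tags <- unlist(tags)
    ci <- .cap_info(truth)
    in_cap <- .in_cap(cand, ci)
    w <- ifelse(in_cap, 1 - cfg$pole_sparsity, 1)
    n_target <- round(stats::runif(1, cfg$manual_points_range[1],
                                   cfg$manual_points_range[2]))
    idx <- sample.int(nrow(cand), n_target,
                      replace = n_target > nrow(cand), prob = w)
    pts <- cand[idx, , drop = FALSE]
    sd_pt <- cfg$point_noise_sd_mm *
      ifelse(in_cap[idx], cfg$cap_noise_factor, 1)
    pts <- pts + matrix(stats::rnorm(3 * nrow(pts), 0, sd_pt), ncol = 3) +
      .expert_bias(pts, ctr, expert)
    point_annotation(patient_id, expert$id, method, session, pts,
                     lm, tags[idx])
  })
}

#' Simulate one semi-automatic segmentation session
#'
#' Emulates the interactive protocol: the expert places the three noisy
#' landmarks, a shape-prior mesh is generated from them alone, and the
#' expert then adds correction points where the current surface deviates
#' most from the (noisily perceived) true boundary, each batch triggering
#' a deformable-model refinement. Returns the final mesh together with the
#' accumulated point annotation.
#'
#' @param truth ground-truth `triangle_mesh`.
#' @param ssm the `statistical_shape_model` prior.
#' @param expert an [expert_profile()].
#' @param cfg a `cohort_config`.
#' @param seed RNG seed.
#' @param session repeat index.
#' @param patient_id identifier.
#' @param batch_size correction points added between refinements.
#' @return a `segmentation_record` with provenance
#'   `"semi_auto_soft_SSM"`.
#' @export
simulate_semiauto_session <- function(truth, ssm, expert, cfg, seed,
                                      session = 0, patient_id = "P",
                                      batch_size = 8) {
  .assert_mesh(truth); .assert_ssm(ssm)
  with_seed(seed, {
    ctr <- colMeans(truth$vertices)
    lm <- .noisy_landmarks(truth, expert, cfg)
    ann0 <- point_annotation(patient_id, expert$id, "semi_auto", session,
                             matrix(numeric(0), ncol = 3), lm)
    current <- fit_soft_ssm(ssm, ann0, cfg$soft_cfg)
    n_total <- round(stats::runif(1, cfg$semi_auto_points_range[1],
                                  cfg$semi_auto_points_range[2]))
    n_corr <- max(n_total - 3L, 0L)
    acc <- matrix(numeric(0), ncol = 3)
    ci <- .cap_info(truth)
    while (nrow(acc) < n_corr) {
      k <- min(batch_size, n_corr - nrow(acc))
      # the expert's attention follows the same slice-visibility pattern
      # as manual placement: corrections are rarer inside the pole caps
      cand0 <- sample_surface_points(truth, 400)
      w_cand <- ifelse(.in_cap(cand0, ci), 1 - cfg$pole_sparsity, 1)
      cand <- cand0[sample.int(400, 150, prob = w_cand), , drop = FALSE]
      d <- closest_points(cand, current)$distance
      # error-weighted choice: corrections favour visibly wrong regions
      # but keep covering the whole gland, as an expert scanning slices
      # does (pure argmax picking would cluster all points in one spot)
      pick <- sample.int(length(d), k, prob = d^2 + 1e-6)
      sel <- cand[pick, , drop = FALSE]
      sd_pt <- cfg$point_noise_sd_mm *
        ifelse(.in_cap(sel, ci), cfg$cap_noise_factor, 1)
      new_pts <- sel + matrix(stats::rnorm(3 * k, 0, sd_pt), ncol = 3) +
        .expert_bias(sel, ctr, expert)
      current <- incremental_refine(current, ssm, new_pts, cfg$soft_cfg,
                                    accumulated = acc, landmarks = lm)
      acc <- rbind(acc, new_pts)
    }
    ann <- point_annotation(patient_id, expert$id, "semi_auto", session,
                            acc, lm)
    segmentation_record(ann, current, "semi_auto_soft_SSM")
  })
}

#' Segmentation record
#'
#' The unit being counted in the study design: one annotation (and, for
#' semi-automatic or reconstructed sessions, its mesh) with a provenance
#' tag.
#' @param annotation a `point_annotation`.
#' @param mesh a `triangle_mesh` or NULL (manual point sessions).
#' @param provenance one of "manual_points", "manual_SSM",
#'   "manual_soft_SSM", "semi_auto_soft_SSM", "consensus".
#' @return a `segmentation_record`.
#' @export
segmentation_record <- function(annotation, mesh = NULL,
                                provenance = "manual_points") {
  provenance <- match.arg(provenance,
    c("manual_points", "manual_SSM", "manual_soft_SSM",
      "semi_auto_soft_SSM", "consensus"))
  .assert_annotation(annotation)
  if (provenance == "manual_points" && !is.null(mesh))
    stop("manual_points records carry no mesh")
  if (provenance != "manual_points" && is.null(mesh))
    stop("provenance ", provenance, " requires a mesh")
  if (!is.null(mesh)) .assert_mesh(mesh)
  structure(list(annotation = annotation, mesh = mesh,
                 provenance = provenance),
            class = "segmentation_record")
}

#' Expected record counts implied by a cohort configuration
#'
#' The pure design arithmetic (no simulation): how many manual,
#' manual-bis, semi-automatic and semi-automatic-bis sessions the
#' allocation rules produce. Non-shared patients are dealt round-robin to
#' the experts; each expert's manual load is capped.
#' @param cfg a `cohort_config`.
#' @return list of counts: `manual`, `manual_bis`, `semi_auto`,
#'   `semi_auto_bis`, `total`, and `per_expert` data frame.
#' @export
cohort_design <- function(cfg) {
  E <- cfg$n_experts; S <- cfg$shared_subset_size
  extras_pool <- cfg$n_patients - S
  extras <- pmax(0, floor((extras_pool + E - seq_len(E)) / E))
  manual_pe <- pmin(S + extras, cfg$max_manual_per_expert)
  semiauto_pe <- S + extras
  bis_pe <- rep(cfg$bis_subset_size, E)
  sa_bis_pe <- c(rep(cfg$bis_subset_size, cfg$n_semiauto_bis_experts),
                 rep(0, E - cfg$n_semiauto_bis_experts))
  per_expert <- data.frame(expert = seq_len(E), manual = manual_pe,
                           manual_bis = bis_pe, semi_auto = semiauto_pe,
                           semi_auto_bis = sa_bis_pe)
  list(manual = sum(manual_pe), manual_bis = sum(bis_pe),
       semi_auto = sum(semiauto_pe), semi_auto_bis = sum(sa_bis_pe),
       total = sum(manual_pe) + sum(bis_pe) + sum(semiauto_pe) +
         sum(sa_bis_pe),
       per_expert = per_expert)
}

#' Generate a full synthetic multi-expert cohort
#'
#' Produces the complete study design: per-expert manual point sessions
#' (points only; reconstruction happens downstream), semi-automatic
#' sessions with fitted meshes, the all-expert shared subset, and repeat
#' ("bis") sessions for intra-observer analysis. Everything is a
#' deterministic function of `cfg` (including its seed).
#'
#' @param cfg a `cohort_config`.
#' @param ssm optional `statistical_shape_model`; built with
#'   [build_toy_ssm()] from the config seed when missing.
#' @param out_dir optional directory: annotations are written as CSV,
#'   meshes as PLY, plus a JSON manifest.
#' @return a `cohort` list: `config`, `ssm`, `truths` (named list of
#'   ground-truth meshes), `experts`, `records` (list of
#'   `segmentation_record`), `manifest` (data frame of record metadata).
#' @export
generate_cohort <- function(cfg, ssm = NULL, out_dir = NULL) {
  if (!inherits(cfg, "cohort_config")) stop("cfg must be a cohort_config")
  if (is.null(ssm)) ssm <- build_toy_ssm(seed = cfg$seed)
  design <- cohort_design(cfg)
  E <- cfg$n_experts; S <- cfg$shared_subset_size
  pids <- sprintf("P%03d", seq_len(cfg$n_patients))
  experts <- lapply(seq_len(E), function(e)
    expert_profile(LETTERS[e], cfg, .derive_seed(cfg$seed, 90000 + e)))
  names(experts) <- vapply(experts, `[[`, "", "id")
  # allocation: shared subset to everyone, remainder round-robin
  alloc <- stats::setNames(vector("list", E), names(experts))
  for (e in seq_len(E)) {
    own <- if (cfg$n_patients - S >= e)
      pids[S + seq(e, cfg$n_patients - S, by = E)] else character(0)
    manual_extra_cap <- max(0, cfg$max_manual_per_expert - S)
    alloc[[e]] <- list(shared = pids[seq_len(S)],
                       extra = own,
                       manual_extra = own[seq_len(min(length(own),
                                                      manual_extra_cap))])
  }
  # only simulate truths for patients that are annotated at all
  used <- unique(c(pids[seq_len(S)],
                   unlist(lapply(alloc, `[[`, "extra"))))
  truths <- stats::setNames(lapply(seq_along(used), function(i)
    simulate_patient(ssm, .derive_seed(cfg$seed, match(used[i], pids)))),
    used)
  records <- list()
  meta <- list()
  k <- 0L
  add_rec <- function(rec) {
    k <<- k + 1L
    records[[k]] <<- rec
    a <- rec$annotation
    meta[[k]] <<- data.frame(record = k, patient_id = a$patient_id,
                             expert_id = a$expert_id, method = a$method,
                             session = a$session,
                             provenance = rec$provenance,
                             n_points = nrow(a$points))
  }
  bis_pids <- pids[seq_len(cfg$bis_subset_size)]
  for (e in seq_len(E)) {
    ex <- experts[[e]]
    manual_pids <- c(alloc[[e]]$shared, alloc[[e]]$manual_extra)
    for (p in manual_pids) {
      sd_ <- .derive_seed(cfg$seed, 1000L * e + match(p, pids))
      ann <- simulate_manual_annotation(truths[[p]], ex, cfg, sd_,
                                        session = 0, patient_id = p)
      add_rec(segmentation_record(ann, NULL, "manual_points"))
    }
    for (p in bis_pids) {
      sd_ <- .derive_seed(cfg$seed, 200000L + 1000L * e + match(p, pids))
      ann <- simulate_manual_annotation(truths[[p]], ex, cfg, sd_,
                                        session = 1, patient_id = p)
      add_rec(segmentation_record(ann, NULL, "manual_points"))
    }
    sa_pids <- c(alloc[[e]]$shared, alloc[[e]]$extra)
    for (p in sa_pids) {
      sd_ <- .derive_seed(cfg$seed, 400000L + 1000L * e + match(p, pids))
      add_rec(simulate_semiauto_session(truths[[p]], ssm, ex, cfg, sd_,
                                        session = 0, patient_id = p))
    }
    if (e <= cfg$n_semiauto_bis_experts) {
      for (p in bis_pids) {
        sd_ <- .derive_seed(cfg$seed, 600000L + 1000L * e + match(p, pids))
        add_rec(simulate_semiauto_session(truths[[p]], ssm, ex, cfg, sd_,
                                          session = 1, patient_id = p))
      }
    }
  }
  manifest <- do.call(rbind, meta)
  stopifnot(nrow(manifest) == design$total)
  cohort <- structure(list(config = cfg, ssm = ssm, truths = truths,
                           experts = experts, records = records,
                           manifest = manifest),
                      class = "cohort")
  if (!is.null(out_dir)) write_cohort(cohort, out_dir)
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", length(x$truths), "patients,",
      length(x$experts), "experts,", length(x$records), "records\n")
  invisible(x)
}

#' Persist a cohort to disk (CSV annotations, PLY meshes, JSON manifest)
#' @param cohort a `cohort`.
#' @param out_dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ann_dir <- file.path(out_dir, "annotations")
  mesh_dir <- file.path(out_dir, "meshes")
  dir.create(ann_dir, showWarnings = FALSE)
  dir.create(mesh_dir, showWarnings = FALSE)
  mf <- cohort$manifest
  mf$annotation_file <- NA_character_
  mf$mesh_file <- NA_character_
  for (i in seq_len(nrow(mf))) {
    rec <- cohort$records[[i]]
    a <- rec$annotation
    stem <- sprintf("%s_%s_%s_s%d", a$patient_id, a$expert_id, a$method,
                    a$session)
    af <- file.path("annotations", paste0(stem, ".csv"))
    write_annotation_csv(a, file.path(out_dir, af))
    mf$annotation_file[i] <- af
    if (!is.null(rec$mesh)) {
      mfile <- file.path("meshes", paste0(stem, ".ply"))
      write_mesh(rec$mesh, file.path(out_dir, mfile))
      mf$mesh_file[i] <- mfile
    }
  }
  for (p in names(cohort$truths))
    write_mesh(cohort$truths[[p]],
               file.path(mesh_dir, paste0(p, "_truth.ply")))
  manifest <- list(config = unclass(cohort$config)[
                     setdiff(names(cohort$config), "soft_cfg")],
                   soft_cfg = unclass(cohort$config$soft_cfg),
                   seed = cohort$config$seed,
                   records = mf)
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Hash of a cohort manifest (determinism check)
#' @param cohort a `cohort`.
#' @return md5 hash string of the serialized manifest (config + record
#'   metadata + truth vertex coordinates rounded to 1e-9 mm).
#' @export
cohort_manifest_hash <- function(cohort) {
  payload <- list(config = unclass(cohort$config)[
                    setdiff(names(cohort$config), "soft_cfg")],
                  manifest = cohort$manifest,
                  truths = lapply(cohort$truths,
                                  function(m) round(m$vertices, 9)))
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = 12,
                       dataframe = "rows")
  unname(tools::md5sum(tmp))
}
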