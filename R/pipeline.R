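#' Run the complete variability study on a synthetic cohort
#'
#' Orchestrates every analysis stage on a generated cohort and emits the
#' result tables:
#' \enumerate{
#'   \item manual reconstructions by both meshing methods (strict
#'     shape-model fit and soft deformable fit);
#'   \item inter-individual manual variability: each expert's points
#'     against every other expert's reconstructed mesh, per method
#'     (points-to-mesh ASD — manual sessions have no intrinsic mesh, so
#'     this asymmetric form is the defined comparison);
#'   \item intra-individual manual variability via repeat ("bis")
#'     sessions;
#'   \item meshing-method intrinsic impact: each expert's points against
#'     their own reconstructed mesh, per method;
#'   \item semi-automatic pairwise ASD / Dice / Hausdorff;
#'   \item leave-one-out STAPLE-like consensus comparisons;
#'   \item manual points against other experts' semi-automatic meshes and
#'     against the all-expert consensus;
#'   \item Wilcoxon tests (Bonferroni-corrected, family of three) on the
#'     strict-vs-soft contrasts of stages 2-4;
#'   \item spatial point-density and ASD maps on the mean shape.
#' }
#'
#' @param cohort a `cohort` from [generate_cohort()], or a directory
#'   written by [write_cohort()] (regenerated deterministically from its
#'   manifest config).
#' @param voxel_mm Dice voxel size (mm).
#' @param bandwidth_mm kernel bandwidth of the spatial maps (mm).
#' @param out_dir optional output directory for CSV tables, JSON summary
#'   and PLY maps.
#' @return a `study_results` list: `tables` (named list of per-comparison
#'   data frames), `summaries` (median/IQR/n per table), `tests`,
#'   `effect_sizes`, `maps` (density map, ASD map, their Spearman rank
#'   correlation), `audit` (comparison counts implied by the manifest).
#' @export
run_variability_study <- function(cohort, voxel_mm = 0.46,
                                  bandwidth_mm = 5, out_dir = NULL) {
  if (is.character(cohort)) cohort <- .read_cohort(cohort)
  if (!inherits(cohort, "cohort")) stop("not a cohort")
  ssm <- cohort$ssm
  mf <- cohort$manifest
  recs <- cohort$records
  key <- function(p, e, s) paste(p, e, s, sep = "|")
  manual_idx <- which(mf$method == "manual")
  semi_idx <- which(mf$method == "semi_auto")

  # ---- stage 1: manual reconstructions (both methods)
  recon <- new.env(parent = emptyenv())
  for (i in manual_idx) {
    a <- recs[[i]]$annotation
    strict <- fit_ssm_to_points(ssm, a)$mesh
    soft <- fit_soft_ssm(ssm, a, cohort$config$soft_cfg)
    recon[[key(a$patient_id, a$expert_id, a$session)]] <-
      list(SSM = strict, soft_SSM = soft)
  }
  manual0 <- mf[mf$method == "manual" & mf$session == 0, ]
  methods <- c("SSM", "soft_SSM")

  rows <- function(...) do.call(rbind, Filter(Negate(is.null), list(...)))
  tables <- list()

  # ---- stage 2: inter-individual manual (points vs other expert's mesh)
  inter <- list()
  for (p in unique(manual0$patient_id)) {
    ex <- manual0$expert_id[manual0$patient_id == p]
    if (length(ex) < 2) next
    for (ei in ex) for (ej in setdiff(ex, ei)) {
      pts <- annotation_points(recs[[
        which(mf$patient_id == p & mf$expert_id == ei &
              mf$method == "manual" & mf$session == 0)]]$annotation)
      for (m_ in methods) {
        inter[[length(inter) + 1]] <- data.frame(
          patient_id = p, expert_points = ei, expert_mesh = ej,
          method = m_,
          asd = asd_points_to_mesh(pts, recon[[key(p, ej, 0)]][[m_]]))
      }
    }
  }
  tables$manual_inter <- do.call(rbind, inter)

  # ---- stage 3: intra-individual manual (bis points vs own first mesh)
  intra <- list()
  bis <- mf[mf$method == "manual" & mf$session == 1, ]
  for (i in seq_len(nrow(bis))) {
    p <- bis$patient_id[i]; e <- bis$expert_id[i]
    pts <- annotation_points(recs[[bis$record[i]]]$annotation)
    for (m_ in methods)
      intra[[length(intra) + 1]] <- data.frame(
        patient_id = p, expert_id = e, method = m_,
        asd = asd_points_to_mesh(pts, recon[[key(p, e, 0)]][[m_]]))
  }
  tables$manual_intra <- do.call(rbind, intra)

  # ---- stage 4: intrinsic meshing-method impact (own points vs own mesh)
  intr <- list()
  for (i in seq_len(nrow(manual0))) {
    p <- manual0$patient_id[i]; e <- manual0$expert_id[i]
    pts <- annotation_points(recs[[manual0$record[i]]]$annotation)
    for (m_ in methods)
      intr[[length(intr) + 1]] <- data.frame(
        patient_id = p, expert_id = e, method = m_,
        asd = asd_points_to_mesh(pts, recon[[key(p, e, 0)]][[m_]]))
  }
  tables$mesh_method_impact <- do.call(rbind, intr)

  # ---- stage 5: semi-automatic pairwise
  semi0 <- mf[mf$method == "semi_auto" & mf$session == 0, ]
  sa_mesh <- function(p, e) recs[[
    semi0$record[semi0$patient_id == p & semi0$expert_id == e]]]$mesh
  pw <- list()
  for (p in unique(semi0$patient_id)) {
    ex <- sort(semi0$expert_id[semi0$patient_id == p])
    if (length(ex) < 2) next
    for (i in seq_along(ex)) for (j in seq_along(ex)) {
      if (j <= i) next
      met <- mesh_pair_metrics(sa_mesh(p, ex[i]), sa_mesh(p, ex[j]),
                               voxel_mm)
      pw[[length(pw) + 1]] <- data.frame(
        patient_id = p, expert_a = ex[i], expert_b = ex[j],
        asd = met$asd_mesh_mesh, dice = met$dice,
        hausdorff = met$hausdorff)
    }
  }
  tables$semiauto_pairwise <- do.call(rbind, pw)

  # ---- stage 6: leave-one-out STAPLE-like consensus
  loo <- list()
  consensus_all <- list()
  for (p in unique(semi0$patient_id)) {
    ex <- sort(semi0$expert_id[semi0$patient_id == p])
    if (length(ex) >= 2)
      consensus_all[[p]] <- staple_mesh_consensus(
        lapply(ex, sa_mesh, p = p))$consensus
    if (length(ex) < 3) next
    for (e in ex) {
      cons <- staple_mesh_consensus(
        lapply(setdiff(ex, e), sa_mesh, p = p))$consensus
      met <- mesh_pair_metrics(sa_mesh(p, e), cons, voxel_mm)
      loo[[length(loo) + 1]] <- data.frame(
        patient_id = p, expert_id = e, asd = met$asd_mesh_mesh,
        dice = met$dice, hausdorff = met$hausdorff)
    }
  }
  tables$semiauto_staple <- do.call(rbind, loo)

  # semi-auto intra (bis)
  sa_bis <- mf[mf$method == "semi_auto" & mf$session == 1, ]
  sab <- list()
  for (i in seq_len(nrow(sa_bis))) {
    p <- sa_bis$patient_id[i]; e <- sa_bis$expert_id[i]
    first <- semi0$record[semi0$patient_id == p & semi0$expert_id == e]
    if (!length(first)) next
    met <- mesh_pair_metrics(recs[[sa_bis$record[i]]]$mesh,
                             recs[[first]]$mesh, voxel_mm)
    sab[[length(sab) + 1]] <- data.frame(
      patient_id = p, expert_id = e, asd = met$asd_mesh_mesh,
      dice = met$dice, hausdorff = met$hausdorff)
  }
  tables$semiauto_intra <- do.call(rbind, sab)

  # ---- stage 7: manual vs semi-automatic
  mvs <- list(); mvc <- list()
  for (i in seq_len(nrow(manual0))) {
    p <- manual0$patient_id[i]; e <- manual0$expert_id[i]
    pts <- annotation_points(recs[[manual0$record[i]]]$annotation)
    others <- setdiff(semi0$expert_id[semi0$patient_id == p], e)
    for (ej in others)
      mvs[[length(mvs) + 1]] <- data.frame(
        patient_id = p, expert_points = e, expert_mesh = ej,
        asd = asd_points_to_mesh(pts, sa_mesh(p, ej)))
    if (!is.null(consensus_all[[p]]))
      mvc[[length(mvc) + 1]] <- data.frame(
        patient_id = p, expert_points = e,
        asd = asd_points_to_mesh(pts, consensus_all[[p]]))
  }
  tables$manual_vs_semiauto_pairwise <- do.call(rbind, mvs)
  tables$manual_vs_consensus <- do.call(rbind, mvc)

  # ---- stage 8: Wilcoxon + Bonferroni on the strict-vs-soft contrasts
  paired_tab <- function(tab) {
    x <- tab$asd[tab$method == "SSM"]
    y <- tab$asd[tab$method == "soft_SSM"]
    list(test = if (length(x) >= 3)
           compare_groups(x, y, paired = TRUE, n_comparisons = 3),
         effect = if (length(x) >= 2) .d_from_samples(x, y))
  }
  tests <- list(manual_inter = paired_tab(tables$manual_inter),
                manual_intra = paired_tab(tables$manual_intra),
                mesh_method_impact = paired_tab(tables$mesh_method_impact))

  # ---- stage 9: spatial maps
  ref <- ssm$mean_shape
  mapped <- list(); vals <- list()
  for (i in seq_len(nrow(manual0))) {
    p <- manual0$patient_id[i]
    if (is.null(consensus_all[[p]])) next
    a <- recs[[manual0$record[i]]]$annotation
    d <- closest_points(a$points, consensus_all[[p]])$distance
    reg <- register_annotation_to_reference(a, ssm)
    mapped[[length(mapped) + 1]] <- reg$mapped
    vals[[length(vals) + 1]] <- d
  }
  maps <- NULL
  if (length(mapped)) {
    mp <- do.call(rbind, mapped); vv <- unlist(vals)
    dens <- surface_density_map(ref, mp, bandwidth_mm)
    asdm <- surface_asd_map(ref, mp, vv, bandwidth_mm)
    ok <- !is.na(asdm$per_vertex_value)
    rho <- stats::cor(dens$per_vertex_value[ok],
                      asdm$per_vertex_value[ok], method = "spearman")
    maps <- list(density = dens, asd = asdm, spearman_rho = rho)
  }

  # ---- summaries and audit
  summaries <- .summarize_tables(tables)
  audit <- .audit_counts(mf)
  for (nm in names(audit)) {
    got <- if (is.null(tables[[nm]])) 0L else nrow(tables[[nm]])
    if (got != audit[[nm]])
      stop("comparison count mismatch in ", nm, ": ", got,
           " rows vs ", audit[[nm]], " expected from the manifest")
  }
  out <- structure(list(tables = tables, summaries = summaries,
                        tests = tests,
                        effect_sizes = lapply(tests, `[[`, "effect"),
                        maps = maps, audit = audit),
                   class = "study_results")
  if (!is.null(out_dir)) .write_study_results(out, out_dir)
  out
}

.d_from_samples <- function(x, y) {
  sx <- summarize_metric(x); sy <- summarize_metric(y)
  cohens_d(sx$median, sigma_from_iqr(sx$iqr_high - sx$iqr_low),
           sy$median, sigma_from_iqr(sy$iqr_high - sy$iqr_low),
           sd_source = "iqr_approx")
}

.summarize_tables <- function(tables) {
  out <- list()
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    if (is.null(tab) || !nrow(tab)) next
    if ("method" %in% names(tab)) {
      for (m_ in unique(tab$method)) {
        s <- summarize_metric(tab$asd[tab$method == m_],
                              paste0(nm, "_", m_))
        out[[length(out) + 1]] <- data.frame(
          table = nm, method = m_, metric = "asd", median = s$median,
          iqr_low = s$iqr_low, iqr_high = s$iqr_high, n = s$n)
      }
    } else {
      for (metric in intersect(c("asd", "dice", "hausdorff"), names(tab))) {
        v <- tab[[metric]][is.finite(tab[[metric]])]
        if (!length(v)) next
        s <- summarize_metric(v, paste0(nm, "_", metric))
        out[[length(out) + 1]] <- data.frame(
          table = nm, method = NA_character_, metric = metric,
          median = s$median, iqr_low = s$iqr_low, iqr_high = s$iqr_high,
          n = s$n)
      }
    }
  }
  do.call(rbind, out)
}

# comparison counts implied by the cohort manifest (the audit oracle)
.audit_counts <- function(mf) {
  manual0 <- mf[mf$method == "manual" & mf$session == 0, ]
  semi0 <- mf[mf$method == "semi_auto" & mf$session == 0, ]
  m_p <- table(manual0$patient_id)
  s_p <- table(semi0$patient_id)
  inter <- sum(m_p * (m_p - 1)) * 2          # ordered pairs x 2 methods
  intra <- sum(mf$method == "manual" & mf$session == 1) * 2
  intrinsic <- nrow(manual0) * 2
  pairwise <- sum(s_p * (s_p - 1) / 2)
  loo <- sum(s_p[s_p >= 3])
  mvs <- 0L; mvc <- 0L
  for (i in seq_len(nrow(manual0))) {
    p <- manual0$patient_id[i]; e <- manual0$expert_id[i]
    sa_ex <- semi0$expert_id[semi0$patient_id == p]
    mvs <- mvs + sum(sa_ex != e)
    if (length(sa_ex) >= 2) mvc <- mvc + 1L
  }
  sa_bis <- mf[mf$method == "semi_auto" & mf$session == 1, ]
  sab <- 0L
  for (i in seq_len(nrow(sa_bis)))
    sab <- sab + as.integer(any(semi0$patient_id == sa_bis$patient_id[i] &
                                semi0$expert_id == sa_bis$expert_id[i]))
  list(manual_inter = inter, manual_intra = intra,
       mesh_method_impact = intrinsic, semiauto_pairwise = pairwise,
       semiauto_staple = loo, semiauto_intra = sab,
       manual_vs_semiauto_pairwise = mvs, manual_vs_consensus = mvc)
}

#' @export
print.study_results <- function(x, ...) {
  cat("study_results with", length(x$tables), "tables\n")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

.write_study_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(res$tables))
    if (!is.null(res$tables[[nm]]))
      utils::write.csv(res$tables[[nm]],
                       file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  utils::write.csv(res$summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  summary_json <- list(
    summaries = res$summaries,
    tests = lapply(res$tests, function(t)
      list(p_value = t$test$p_value, p_adjusted = t$test$p_adjusted,
           d = t$effect$d, classification = t$effect$classification,
           skipped = is.null(t$test))),
    audit = res$audit,
    spatial_spearman_rho = if (!is.null(res$maps)) res$maps$spearman_rho)
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(res$maps)) {
    write_surface_map(res$maps$density,
                      ply_path = file.path(out_dir, "density_map.ply"),
                      csv_path = file.path(out_dir, "density_map.csv"))
    write_surface_map(res$maps$asd,
                      ply_path = file.path(out_dir, "asd_map.ply"),
                      csv_path = file.path(out_dir, "asd_map.csv"))
  }
  invisible(out_dir)
}

# regenerate a cohort deterministically from a written manifest
.read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfgl <- manifest$config
  soft <- manifest$soft_cfg
  cfg <- cohort_config(
    n_patients = cfgl$n_patients, n_experts = cfgl$n_experts,
    seed = cfgl$seed, manual_points_range = cfgl$manual_points_range,
    semi_auto_points_range = cfgl$semi_auto_points_range,
    point_noise_sd_mm = cfgl$point_noise_sd_mm,
    expert_bias_sd_mm = cfgl$expert_bias_sd_mm,
    pole_sparsity = cfgl$pole_sparsity,
    cap_noise_factor = cfgl$cap_noise_factor,
    slice_spacing_mm = cfgl$slice_spacing_mm,
    shared_subset_size = cfgl$shared_subset_size,
    bis_subset_size = cfgl$bis_subset_size,
    max_manual_per_expert = cfgl$max_manual_per_expert,
    n_semiauto_bis_experts = cfgl$n_semiauto_bis_experts,
    soft_cfg = soft_fit_config(soft$regularization_weight,
                               soft$control_grid_spacing, soft$max_iter,
                               soft$tol_mm, soft$clamp_modes))
  generate_cohort(cfg)
}

#' Reproduce the cross-study effect-size table
#'
#' Recomputes, from the shipped fixture of printed summary statistics
#' (medians/IQRs for the reference study, means/SDs for the comparison
#' literature), every cross-study Cohen's d via sigma = IQR/1.35 and the
#' two-group pooled SD.
#'
#' @param fixture_path CSV of summaries; defaults to the fixture shipped
#'   with the package.
#' @return the fixture with `d`, `d_raw` and `classification` columns (see
#'   [effect_size_table()]).
#' @export
reproduce_effect_size_table <- function(fixture_path = NULL) {
  if (is.null(fixture_path))
    fixture_path <- system.file("extdata", "cross_study_summaries.csv",
                                package = "prosegvar", mustWork = TRUE)
  summaries <- utils::read.csv(fixture_path, stringsAsFactors = FALSE)
  effect_size_table(summaries)
}
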