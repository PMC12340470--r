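#' Configuration for the soft (deformable) shape-model fit
#'
#' @param regularization_weight nonnegative bending-energy weight; large
#'   values pin the result to the strict subspace fit, small values let the
#'   surface follow the points closely.
#' @param control_grid_spacing B-spline control lattice spacing in mm.
#' @param max_iter maximum correspondence/solve alternations.
#' @param tol_mm stop when the objective improves by less than this.
#' @param clamp_modes clamp the stage-1 mode loadings.
#' @return a `soft_fit_config` list.
#' @export
soft_fit_config <- function(regularization_weight = 0.01,
                            control_grid_spacing = 7,
                            max_iter = 8, tol_mm = 1e-3,
                            clamp_modes = TRUE) {
  if (control_grid_spacing <= 0) stop("control_grid_spacing must be > 0")
  if (regularization_weight < 0) stop("regularization_weight must be >= 0")
  structure(list(regularization_weight = regularization_weight,
                 control_grid_spacing = control_grid_spacing,
                 max_iter = max_iter, tol_mm = tol_mm,
                 clamp_modes = clamp_modes),
            class = "soft_fit_config")
}

# cubic uniform B-spline basis values for fractional offset t in [0,1)
.bspline_basis <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

# Free-form deformation lattice over a bounding box. Control nodes are on
# a regular grid with two margin layers so every point in the box has full
# cubic support.
.make_lattice <- function(lo, hi, spacing) {
  n <- pmax(as.integer(ceiling((hi - lo) / spacing)) + 6L, 7L)
  origin <- lo - 2 * spacing
  if (prod(n) < 8) stop("control lattice has no interior nodes")
  list(origin = origin, spacing = spacing, dims = n)
}

# design matrix: rows = points, cols = lattice nodes (dense)
.lattice_design <- function(lat, pts) {
  n <- nrow(pts); d <- lat$dims
  u <- sweep(pts, 2, lat$origin) / lat$spacing
  iv <- floor(u)
  tv <- u - iv
  iv <- matrix(as.integer(iv), ncol = 3)
  if (any(iv < 1L) | any(iv[, 1] > d[1] - 3L) | any(iv[, 2] > d[2] - 3L) |
      any(iv[, 3] > d[3] - 3L))
    stop("point outside lattice support")
  Bx <- .bspline_basis(tv[, 1]); By <- .bspline_basis(tv[, 2])
  Bz <- .bspline_basis(tv[, 3])
  B <- matrix(0, n, prod(d))
  for (a in 0:3) for (b in 0:3) for (c_ in 0:3) {
    col <- (iv[, 1] - 1L + a) + d[1] * ((iv[, 2] - 1L + b) +
           d[2] * (iv[, 3] - 1L + c_)) + 1L
    B[cbind(seq_len(n), col)] <- B[cbind(seq_len(n), col)] +
      Bx[, a + 1] * By[, b + 1] * Bz[, c_ + 1]
  }
  B
}

# Lattice regularizer: squared second differences (bending) along each
# axis, a lightly weighted first-difference (membrane) term that removes
# the bending term's affine null space — without it a single local pull
# would extend linearly across the whole lattice — and a small magnitude
# term so the large-weight limit is the identity deformation.
.penalty_cache <- new.env(parent = emptyenv())

.lattice_penalty <- function(lat) {
  d <- lat$dims
  key <- paste(d, collapse = "x")
  cached <- .penalty_cache[[key]]
  if (!is.null(cached)) return(cached)
  N <- prod(d)
  idx <- function(i, j, k) (i - 1L) + d[1] * ((j - 1L) + d[2] * (k - 1L)) + 1L
  D <- matrix(0, N, N)
  add_axis <- function(D, centers, minus, plus) {
    # accumulate (c_minus - 2 c_center + c_plus)^2 quadratic form
    for (r in seq_along(centers)) {
      tri <- c(minus[r], centers[r], plus[r])
      coef <- c(1, -2, 1)
      D[tri, tri] <- D[tri, tri] + outer(coef, coef)
    }
    D
  }
  g <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]), k = seq_len(d[3]))
  for (axis in 1:3) {
    ok <- g[[axis]] > 1 & g[[axis]] < d[axis]
    gi <- g[ok, , drop = FALSE]
    shift <- function(delta) {
      gg <- gi; gg[[axis]] <- gg[[axis]] + delta
      idx(gg$i, gg$j, gg$k)
    }
    D <- add_axis(D, shift(0L), shift(-1L), shift(1L))
    # membrane (first-difference) term
    ok1 <- g[[axis]] < d[axis]
    g1 <- g[ok1, , drop = FALSE]
    shift1 <- function(delta) {
      gg <- g1; gg[[axis]] <- gg[[axis]] + delta
      idx(gg$i, gg$j, gg$k)
    }
    lo <- shift1(0L); hi <- shift1(1L)
    for (r in seq_along(lo)) {
      tri <- c(lo[r], hi[r])
      D[tri, tri] <- D[tri, tri] + 2.0 * outer(c(1, -1), c(1, -1))
    }
  }
  D <- D + diag(1e-2, N)
  if (length(ls(.penalty_cache)) >= 6)
    rm(list = ls(.penalty_cache), envir = .penalty_cache)
  .penalty_cache[[key]] <- D
  D
}

# Core free-form refinement: warp `base` toward `targets` with a cubic
# B-spline displacement field. Returns the warped mesh plus the objective
# trace (data term + weight * penalty).
.ffd_refine <- function(base, targets, cfg) {
  .assert_mesh(base)
  targets <- as.matrix(targets)
  if (nrow(targets) == 0L) stop("no attraction points")
  box <- rbind(apply(rbind(base$vertices, targets), 2, min),
               apply(rbind(base$vertices, targets), 2, max))
  lat <- .make_lattice(box[1, ], box[2, ], cfg$control_grid_spacing)
  Bv <- .lattice_design(lat, base$vertices)
  # active nodes: those supporting any base vertex or target point
  active <- which(colSums(abs(Bv)) > 0 |
                  colSums(abs(.lattice_design(lat, targets))) > 0)
  D <- .lattice_penalty(lat)[active, active, drop = FALSE]
  w <- cfg$regularization_weight
  N <- length(active)
  coef <- matrix(0, N, 3)
  obj_of <- function(coef) {
    disp <- Bv[, active, drop = FALSE] %*% coef
    warped <- base
    warped$vertices <- base$vertices + disp
    cp <- closest_points(targets, warped)
    list(obj = sum(cp$distance^2) + w * sum(diag(crossprod(coef, D %*% coef))),
         warped = warped, cp = cp)
  }
  state <- obj_of(coef)
  trace <- state$obj
  best <- list(coef = coef, state = state)
  for (it in seq_len(cfg$max_iter)) {
    cp <- state$cp
    Fc <- state$warped$faces[cp$face, , drop = FALSE]
    bw <- cp$bary
    # footpoints expressed on the undeformed base surface
    s0 <- bw[, 1] * base$vertices[Fc[, 1], , drop = FALSE] +
          bw[, 2] * base$vertices[Fc[, 2], , drop = FALSE] +
          bw[, 3] * base$vertices[Fc[, 3], , drop = FALSE]
    Bs <- .lattice_design(lat, s0)[, active, drop = FALSE]
    A <- crossprod(Bs) + w * D
    R_ <- crossprod(Bs, targets - s0)
    ch <- chol(A + diag(1e-9, N))
    coef_new <- backsolve(ch, forwardsolve(t(ch), R_))
    state_new <- obj_of(coef_new)
    if (state_new$obj > best$state$obj - cfg$tol_mm^2) {
      if (state_new$obj < best$state$obj)
        best <- list(coef = coef_new, state = state_new)
      trace <- c(trace, state_new$obj)
      break
    }
    coef <- coef_new; state <- state_new
    trace <- c(trace, state$obj)
    best <- list(coef = coef, state = state)
  }
  out <- best$state$warped
  attr(out, "objective_trace") <- trace
  attr(out, "mean_residual_mm") <- mean(best$state$cp$distance)
  attr(out, "ffd_base") <- base
  out
}

#' Soft shape-model fit: shape prior plus B-spline deformation
#'
#' Two-stage reconstruction of a surface from sparse expert points (the
#' "soft-SSM" method used for both manual reconstructions and the
#' semi-automatic pipeline). Stage 1 fits the strict statistical shape
#' model ([fit_ssm_to_points()]). Stage 2 warps the stage-1 mesh with a
#' smooth free-form deformation (cubic B-spline lattice over the bounding
#' box) minimizing the sum of squared point-to-surface distances plus
#' `regularization_weight` times the lattice bending energy. The output
#' keeps the model topology and is fully deterministic.
#'
#' @param ssm a `statistical_shape_model`.
#' @param a a `point_annotation` with landmarks.
#' @param cfg a [soft_fit_config()].
#' @return a `triangle_mesh` with attributes `objective_trace` and
#'   `mean_residual_mm`; the stage-1 strict fit is attached as attribute
#'   `strict_fit`.
#' @export
fit_soft_ssm <- function(ssm, a, cfg = soft_fit_config()) {
  .assert_annotation(a)
  stage1 <- fit_ssm_to_points(ssm, a, clamp = cfg$clamp_modes)
  targets <- annotation_points(a)
  out <- .ffd_refine(stage1$mesh, targets, cfg)
  attr(out, "strict_fit") <- stage1
  out
}

#' Incrementally refine a fitted mesh with additional points
#'
#' Re-runs the stage-2 free-form deformation with the accumulated
#' attraction point set including the new points; used by the
#' semi-automatic session simulator to emulate an expert adding correction
#' points one batch at a time. The deformation is always recomputed from
#' the mesh's original (pre-deformation) base — carried as an attribute by
#' [fit_soft_ssm()] — so the result depends on the accumulated point set,
#' not on the order in which points arrived. A mesh without that attribute
#' is deformed directly.
#'
#' @param current a `triangle_mesh` on the model topology.
#' @param ssm the `statistical_shape_model` (kept for interface symmetry;
#'   the deformation operates on the mesh directly).
#' @param new_points matrix (or length-3 vector) of new attraction points.
#' @param cfg a [soft_fit_config()].
#' @param accumulated optional matrix of previously placed points to keep
#'   attracting.
#' @param landmarks optional 3 x 3 apex/base/posterior matrix. When given,
#'   the full two-stage fit (shape prior + deformation) is re-run on the
#'   accumulated point set, so a sequence of refinements ends at exactly
#'   the mesh a single batch fit of the same points produces.
#' @return refined `triangle_mesh`.
#' @export
incremental_refine <- function(current, ssm, new_points,
                               cfg = soft_fit_config(), accumulated = NULL,
                               landmarks = NULL) {
  if (is.null(dim(new_points))) new_points <- matrix(new_points, ncol = 3)
  targets <- rbind(accumulated, new_points)
  if (!is.null(landmarks)) {
    ann <- point_annotation("incremental", "incremental", "semi_auto", 0,
                            targets, landmarks)
    return(fit_soft_ssm(ssm, ann, cfg))
  }
  base <- attr(current, "ffd_base")
  if (is.null(base)) base <- current
  .ffd_refine(base, targets, cfg)
}
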