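#' Build a statistical shape model from corresponded meshes
#'
#' Generalized (rigid) Procrustes alignment of the training meshes followed
#' by a principal-component decomposition of the stacked vertex
#' coordinates. The model consists of the mean shape, orthonormal modes of
#' variation and their eigenvalues; the number of retained modes is the
#' smallest reaching `variance_retained` of the total variance.
#'
#' All training meshes must share topology (identical face array); dense
#' correspondence on arbitrary clinical meshes is out of scope, as
#' documented in the methods vignette.
#'
#' @param training list of >= 2 `triangle_mesh` objects with shared
#'   topology.
#' @param variance_retained fraction of variance to retain, in (0, 1].
#' @return an object of class `statistical_shape_model`: `mean_shape`
#'   (mesh), `modes` (3V x K orthonormal matrix), `eigenvalues`
#'   (nonincreasing), `n_train`, `alignment` (convention record).
#' @export
build_ssm <- function(training, variance_retained = 0.95) {
  if (length(training) < 2L) stop("need at least 2 training meshes")
  if (variance_retained <= 0 || variance_retained > 1)
    stop("variance_retained must be in (0, 1]")
  F0 <- training[[1]]$faces
  for (m in training) {
    .assert_mesh(m)
    if (!identical(dim(m$vertices), dim(training[[1]]$vertices)) ||
        !identical(m$faces, F0))
      stop("training meshes must share topology")
  }
  nV <- nrow(training[[1]]$vertices)
  # generalized Procrustes: rigid-only (coordinates stay metric mm)
  shapes <- lapply(training, function(m)
    sweep(m$vertices, 2, colMeans(m$vertices)))
  ref <- shapes[[1]]
  for (it in 1:10) {
    aligned <- lapply(shapes, function(S) {
      tr <- procrustes_align(S, ref, allow_scale = FALSE)
      apply_transform(S, tr)
    })
    new_ref <- Reduce(`+`, aligned) / length(aligned)
    new_ref <- sweep(new_ref, 2, colMeans(new_ref))
    if (max(abs(new_ref - ref)) < 1e-9) { ref <- new_ref; shapes <- aligned; break }
    ref <- new_ref; shapes <- aligned
  }
  X <- t(vapply(shapes, as.vector, numeric(3 * nV)))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0)
  n <- length(training)
  evals <- sv$d^2 / (n - 1)
  keep <- evals > max(evals[1], 1e-300) * 1e-10 & evals > 1e-12
  evals <- evals[keep]
  modes <- sv$v[, keep, drop = FALSE]
  if (length(evals)) {
    cum <- cumsum(evals) / sum(evals)
    K <- which(cum >= variance_retained - 1e-12)[1]
    evals <- evals[seq_len(K)]
    modes <- modes[, seq_len(K), drop = FALSE]
  }
  mean_mesh <- triangle_mesh(matrix(mu, ncol = 3), F0,
                             topology_id = training[[1]]$topology_id)
  structure(list(mean_shape = mean_mesh, modes = modes,
                 eigenvalues = evals, n_train = n,
                 alignment = list(method = "generalized Procrustes",
                                  scaling = FALSE,
                                  landmark_rule = .landmark_rule_doc())),
            class = "statistical_shape_model")
}

#' @export
print.statistical_shape_model <- function(x, ...) {
  cat("statistical_shape_model:", nrow(x$mean_shape$vertices), "vertices,",
      length(x$eigenvalues), "modes from", x$n_train, "training shapes\n")
  invisible(x)
}

.assert_ssm <- function(ssm) {
  if (!inherits(ssm, "statistical_shape_model"))
    stop("not a statistical_shape_model")
  invisible(ssm)
}

.face_normals <- function(m) {
  V <- m$vertices; F <- m$faces
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n / pmax(sqrt(rowSums(n^2)), 1e-300)
}

.landmark_rule_doc <- function() {
  paste("apex = min-z surface vertex, base = max-z, posterior = min-y;",
        "model frame: +z toward the bladder base, -y posterior")
}

#' Reference landmarks of a mesh under the package convention
#'
#' In the model frame the cranio-caudal axis is z (base toward +z, apex
#' toward -z) and the posterior direction is -y. The three protocol
#' landmarks are the corresponding extreme surface vertices.
#' @param m a `triangle_mesh` in (or near) the model frame.
#' @return 3 x 3 matrix with rownames apex, base, posterior.
#' @export
mesh_landmarks <- function(m) {
  .assert_mesh(m)
  V <- m$vertices
  out <- rbind(apex = V[which.min(V[, 3]), ],
               base = V[which.max(V[, 3]), ],
               posterior = V[which.min(V[, 2]), ])
  colnames(out) <- NULL
  out
}

#' Generate a shape from the model
#'
#' Mean shape plus the linear combination of modes, then the pose applied.
#' @param ssm a `statistical_shape_model`.
#' @param b numeric vector of K mode loadings.
#' @param pose optional similarity transform (default identity).
#' @param clamp clamp each loading to +/- 3 sqrt(eigenvalue) (the standard
#'   guard against anatomically improbable shapes).
#' @return a `triangle_mesh` on the model topology.
#' @export
sample_ssm <- function(ssm, b, pose = NULL, clamp = FALSE) {
  .assert_ssm(ssm)
  K <- length(ssm$eigenvalues)
  if (length(b) != K)
    stop("coefficient length ", length(b), " != number of modes ", K)
  if (clamp && K) b <- .clamp_coeffs(b, ssm$eigenvalues)
  v <- as.vector(ssm$mean_shape$vertices)
  if (K) v <- v + as.vector(ssm$modes %*% b)
  m <- triangle_mesh(matrix(v, ncol = 3), ssm$mean_shape$faces,
                     topology_id = ssm$mean_shape$topology_id)
  if (!is.null(pose)) m <- transform_mesh(m, pose)
  m
}

.clamp_coeffs <- function(b, evals) {
  lim <- 3 * sqrt(evals)
  pmin(pmax(b, -lim), lim)
}

#' Project a corresponded mesh onto the model subspace
#' @param ssm a `statistical_shape_model`.
#' @param m a `triangle_mesh` on the model topology (model frame).
#' @return list with `b` (loadings) and `residual_rms` (mm), the
#'   out-of-subspace remainder.
#' @export
project_to_ssm <- function(ssm, m) {
  .assert_ssm(ssm); .assert_mesh(m)
  v <- as.vector(m$vertices) - as.vector(ssm$mean_shape$vertices)
  b <- drop(crossprod(ssm$modes, v))
  resid <- v - as.vector(ssm$modes %*% b)
  list(b = b, residual_rms = sqrt(mean(resid^2)))
}

#' Strict shape-model fit to sparse expert points
#'
#' Computes the mesh that lies exactly in the model subspace and is the
#' closest fit to the annotated points (the "manual_SSM" reconstruction).
#' The pose is initialized from the three protocol landmarks against the
#' model landmarks; the algorithm then alternates (i) closest-surface-point
#' correspondence in barycentric coordinates, (ii) a ridge-regularized
#' linear solve for the mode loadings (clamped to +/- 3 sqrt(eigenvalue)),
#' and (iii) a rigid pose update, until the mean point-to-mesh distance
#' changes by less than `tol_mm`. The objective trace is monotone: an
#' iterate that fails to improve is discarded and the best iterate
#' returned.
#'
#' Landmarks participate as ordinary attraction points. With fewer points
#' than modes the solve is rank-deficient and a ridge toward the model
#' prior (weight `1e-3 * mean(eigenvalues)` on the Mahalanobis norm
#' `sum(b_k^2 / lambda_k)`) keeps it stable.
#'
#' @param ssm a `statistical_shape_model`.
#' @param a a `point_annotation`.
#' @param max_iter maximum alternation count.
#' @param tol_mm convergence tolerance on the mean point-to-mesh distance.
#' @param allow_scale include isotropic scale in the pose (default FALSE:
#'   ultrasound coordinates are metric).
#' @param clamp clamp loadings (default TRUE).
#' @return list with `coefficients` (`b`, `pose`), `mesh` (posed fit on the
#'   model topology), `objective_trace` (mean point distance per
#'   iteration), `converged`.
#' @export
fit_ssm_to_points <- function(ssm, a, max_iter = 30, tol_mm = 1e-3,
                              allow_scale = FALSE, clamp = TRUE) {
  .assert_ssm(ssm)
  .assert_annotation(a)
  pts <- annotation_points(a)
  K <- length(ssm$eigenvalues)
  nV <- nrow(ssm$mean_shape$vertices)
  mu <- as.vector(ssm$mean_shape$vertices)
  # ridge toward the model prior: weight 1e-3 * mean(lambda) on the
  # Mahalanobis norm sum(b_k^2 / lambda_k), calibrated to the 3-landmark
  # case and decaying with the point count so dense noiseless fits are
  # essentially unbiased while rank-deficient (sparse) ones stay stable
  ridge_diag <- if (K) {
    1e-3 * mean(ssm$eigenvalues) * 3 / max(nrow(pts), 3) / ssm$eigenvalues
  } else numeric(0)
  model_lm <- mesh_landmarks(ssm$mean_shape)
  pose <- procrustes_align(model_lm, a$landmarks, allow_scale = allow_scale)
  b <- numeric(K)
  n <- nrow(pts)
  best <- NULL
  trace <- numeric(0)
  converged <- FALSE
  idx <- function(c_) (c_ - 1) * n + seq_len(n)
  state_of <- function(b, pose) {
    model_mesh <- sample_ssm(ssm, b)
    q <- apply_transform(pts, invert_transform(pose))
    cp <- closest_points(q, model_mesh)
    list(mesh = model_mesh, cp = cp, obj = mean(cp$distance) * pose$scale)
  }
  state <- state_of(b, pose)
  for (it in seq_len(max_iter)) {
    obj <- state$obj
    trace <- c(trace, obj)
    if (is.null(best) || obj < best$obj)
      best <- list(b = b, pose = pose, obj = obj)
    if (length(trace) > 1 &&
        trace[length(trace) - 1] - obj < tol_mm) {
      converged <- TRUE
      break
    }
    # joint Gauss-Newton step over mode loadings and pose: model-frame
    # footpoints a_i(b) predict data points as s * R a_i + t, linearized
    # in (delta_b, rotation omega, delta_t [, delta_s])
    model_mesh <- state$mesh
    cp <- state$cp
    Fc <- model_mesh$faces[cp$face, , drop = FALSE]
    w <- cp$bary
    Mm <- matrix(0, 3 * n, K)   # model-frame mode Jacobian, rows [x;y;z]
    a0 <- matrix(0, n, 3)       # model-frame footpoints at current b
    cur <- as.vector(model_mesh$vertices)
    for (c_ in 1:3) {
      off <- (c_ - 1) * nV
      if (K)
        Mm[idx(c_), ] <- w[, 1] * ssm$modes[off + Fc[, 1], , drop = FALSE] +
                         w[, 2] * ssm$modes[off + Fc[, 2], , drop = FALSE] +
                         w[, 3] * ssm$modes[off + Fc[, 3], , drop = FALSE]
      a0[, c_] <- w[, 1] * cur[off + Fc[, 1]] +
                  w[, 2] * cur[off + Fc[, 2]] + w[, 3] * cur[off + Fc[, 3]]
    }
    R <- pose$rotation; s <- pose$scale
    pred <- s * a0 %*% t(R)
    pred <- sweep(pred, 2, pose$translation, "+")
    r <- as.vector(pts - pred)           # stacked [x;y;z] residuals
    n_par <- K + 6L + as.integer(allow_scale)
    J <- matrix(0, 3 * n, n_par)
    for (c_ in 1:3) {
      rows <- idx(c_)
      if (K)
        J[rows, seq_len(K)] <- s * (R[c_, 1] * Mm[idx(1), , drop = FALSE] +
                                    R[c_, 2] * Mm[idx(2), , drop = FALSE] +
                                    R[c_, 3] * Mm[idx(3), , drop = FALSE])
      # d/d omega of s R (I + skew(omega)) a0  =  -s R [a0]x
      J[rows, K + 1L] <- s * (R[c_, 3] * a0[, 2] - R[c_, 2] * a0[, 3])
      J[rows, K + 2L] <- s * (R[c_, 1] * a0[, 3] - R[c_, 3] * a0[, 1])
      J[rows, K + 3L] <- s * (R[c_, 2] * a0[, 1] - R[c_, 1] * a0[, 2])
      J[rows, K + 3L + c_] <- 1
      if (allow_scale) J[rows, n_par] <- drop(a0 %*% R[c_, ])
    }
    reg <- c(ridge_diag, rep(1e-10, n_par - K))
    # point-to-plane rows let correspondences slide tangentially (fast
    # ICP convergence); a lightly weighted point-to-point term removes
    # the tangential null space of the plane-only system
    nrm_d <- .face_normals(model_mesh)[cp$face, , drop = FALSE] %*% t(R)
    Jp <- nrm_d[, 1] * J[idx(1), , drop = FALSE] +
          nrm_d[, 2] * J[idx(2), , drop = FALSE] +
          nrm_d[, 3] * J[idx(3), , drop = FALSE]
    rp <- nrm_d[, 1] * r[idx(1)] + nrm_d[, 2] * r[idx(2)] +
          nrm_d[, 3] * r[idx(3)]
    w_pp <- 0.001
    A_gn <- crossprod(Jp) + w_pp * crossprod(J) + diag(reg, n_par)
    rhs <- crossprod(Jp, rp) + w_pp * crossprod(J, r)
    delta <- drop(solve(A_gn, rhs))
    # backtracking keeps the objective trace monotone
    step <- 1
    improved <- FALSE
    for (bt in 1:6) {
      b_try <- b + step * delta[seq_len(K)]
      if (clamp && K) b_try <- .clamp_coeffs(b_try, ssm$eigenvalues)
      om <- step * delta[K + 1:3]
      Rskew <- rbind(c(0, -om[3], om[2]), c(om[3], 0, -om[1]),
                     c(-om[2], om[1], 0))
      R_try <- R %*% (diag(3) + Rskew)
      sv <- svd(R_try)
      R_try <- sv$u %*% t(sv$v)
      pose_try <- list(rotation = R_try,
                       translation = pose$translation + step * delta[K + 4:6],
                       scale = if (allow_scale) s + step * delta[n_par] else s,
                       rmsd = NA_real_)
      state_try <- state_of(b_try, pose_try)
      if (state_try$obj <= obj + 1e-12) {
        b <- b_try; pose <- pose_try; state <- state_try
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
  }
  mesh <- transform_mesh(sample_ssm(ssm, best$b), best$pose)
  if (!converged && length(trace) >= max_iter)
    warning("strict shape-model fit did not converge in ", max_iter,
            " iterations; returning best iterate", call. = FALSE)
  list(coefficients = list(b = best$b, pose = best$pose),
       mesh = mesh, objective_trace = trace, converged = converged)
}
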