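#' Triangle surface mesh
#'
#' Constructs a closed triangulated surface in millimetre coordinates, the
#' unit of segmentation comparison throughout the package. Faces with
#' (numerically) zero area are dropped with a message, mirroring the
#' tolerance of distance-based metrics to slightly imperfect inputs.
#'
#' @param vertices numeric matrix with 3 columns (x, y, z in mm).
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param topology_id optional tag marking shared vertex correspondence
#'   across meshes (all meshes sampled from one shape model carry the same
#'   tag and can be compared vertex-by-vertex).
#' @return an object of class `triangle_mesh` with elements `vertices`,
#'   `faces` and `topology_id`.
#' @export
triangle_mesh <- function(vertices, faces, topology_id = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(vertices) <= 3L) stop("a mesh needs more than 3 vertices")
  if (anyNA(vertices) || any(!is.finite(vertices)))
    stop("vertex coordinates must be finite")
  if (anyNA(faces) || any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  areas <- .face_areas(vertices, faces)
  degen <- areas <= 1e-12
  if (any(degen)) {
    message(sum(degen), " degenerate (zero-area) face(s) dropped")
    faces <- faces[!degen, , drop = FALSE]
  }
  if (nrow(faces) == 0L) stop("mesh has no non-degenerate faces")
  structure(list(vertices = vertices, faces = faces,
                 topology_id = topology_id),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces")
  if (!is.null(x$topology_id)) cat(", topology", x$topology_id)
  cat("\n")
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

.assert_mesh <- function(m, arg = deparse(substitute(m))) {
  if (!is_triangle_mesh(m)) stop(arg, " is not a triangle_mesh")
  invisible(m)
}

.face_areas <- function(V, F) {
  a <- V[F[, 1], , drop = FALSE]
  e1 <- V[F[, 2], , drop = FALSE] - a
  e2 <- V[F[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Face areas of a mesh (mm^2)
#' @param m a `triangle_mesh`.
#' @return numeric vector, one area per face.
#' @export
face_areas <- function(m) {
  .assert_mesh(m)
  .face_areas(m$vertices, m$faces)
}

#' Per-vertex areas (one third of incident face areas)
#' @param m a `triangle_mesh`.
#' @return numeric vector, one area per vertex; sums to the surface area.
#' @export
vertex_areas <- function(m) {
  .assert_mesh(m)
  fa <- face_areas(m) / 3
  va <- numeric(nrow(m$vertices))
  for (k in 1:3) {
    acc <- tapply(fa, m$faces[, k], sum)
    va[as.integer(names(acc))] <- va[as.integer(names(acc))] + acc
  }
  va
}

#' Enclosed volume of a watertight mesh (mm^3)
#'
#' Signed volume by the divergence theorem; positive for consistently
#' outward-oriented surfaces.
#' @param m a `triangle_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(m) {
  .assert_mesh(m)
  V <- m$vertices; F <- m$faces
  a <- V[F[, 1], , drop = FALSE]
  b <- V[F[, 2], , drop = FALSE]
  c <- V[F[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

#' Check whether a mesh is watertight (closed, edge-manifold)
#'
#' Volumetric operations (Dice) require every edge to be shared by exactly
#' two consistently oriented faces.
#' @param m a `triangle_mesh`.
#' @return logical scalar with attribute `n_bad_edges`.
#' @export
is_watertight <- function(m) {
  .assert_mesh(m)
  chk <- cpp_edge_check(m$faces)
  structure(chk$watertight, n_bad_edges = chk$n_bad_edges)
}

#' Apply a rigid/similarity transform to a mesh
#' @param m a `triangle_mesh`.
#' @param transform list with `rotation` (3x3), `translation` (length 3) and
#'   optional `scale`, as returned by [procrustes_align()].
#' @return transformed mesh (same topology).
#' @export
transform_mesh <- function(m, transform) {
  .assert_mesh(m)
  m$vertices <- apply_transform(m$vertices, transform)
  m
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere: the shared topology used
#' by the synthetic shape model and all meshes sampled from it.
#' @param subdiv number of 4-to-1 subdivision rounds (0 = icosahedron).
#' @param radius sphere radius (mm).
#' @param center sphere center (length-3, mm).
#' @return a `triangle_mesh` with topology tag `"ico<subdiv>"`.
#' @export
icosphere <- function(subdiv = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  V <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  F <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  V <- V / sqrt(rowSums(V^2))
  for (s in seq_len(subdiv)) {
    edge_mid <- new.env(hash = TRUE)
    nv <- nrow(V)
    newV <- list()
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edge_mid[[key]]
      if (!is.null(idx)) return(idx)
      p <- (V[i, ] + V[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      newV[[length(newV) + 1L]] <<- p
      idx <- nv + length(newV)
      edge_mid[[key]] <- idx
      idx
    }
    newF <- matrix(0L, nrow(F) * 4, 3)
    for (f in seq_len(nrow(F))) {
      i <- F[f, 1]; j <- F[f, 2]; k <- F[f, 3]
      ij <- midpoint(i, j); jk <- midpoint(j, k); ki <- midpoint(k, i)
      newF[4 * f - 3, ] <- c(i, ij, ki)
      newF[4 * f - 2, ] <- c(j, jk, ij)
      newF[4 * f - 1, ] <- c(k, ki, jk)
      newF[4 * f, ] <- c(ij, jk, ki)
    }
    V <- rbind(V, do.call(rbind, newV))
    F <- newF
  }
  V <- V * radius
  V <- sweep(V, 2, center, "+")
  triangle_mesh(V, F, topology_id = paste0("ico", subdiv))
}

#' Triaxial ellipsoid mesh on icosphere topology
#' @param semi_axes length-3 semi-axes (mm).
#' @param subdiv icosphere subdivision level.
#' @param center center (mm).
#' @return a `triangle_mesh`.
#' @export
ellipsoid_mesh <- function(semi_axes, subdiv = 3, center = c(0, 0, 0)) {
  m <- icosphere(subdiv = subdiv, radius = 1)
  m$vertices <- sweep(m$vertices, 2, semi_axes, "*")
  m$vertices <- sweep(m$vertices, 2, center, "+")
  m
}

#' Uniform random points on a mesh surface
#'
#' Area-weighted face choice with uniform barycentric sampling; uses the
#' current RNG state.
#' @param m a `triangle_mesh`.
#' @param n number of points.
#' @return n x 3 matrix of surface points.
#' @export
sample_surface_points <- function(m, n) {
  .assert_mesh(m)
  fa <- face_areas(m)
  f <- sample.int(nrow(m$faces), n, replace = TRUE, prob = fa)
  r1 <- sqrt(stats::runif(n)); r2 <- stats::runif(n)
  u <- 1 - r1; v <- r1 * (1 - r2); w <- r1 * r2
  a <- m$vertices[m$faces[f, 1], , drop = FALSE]
  b <- m$vertices[m$faces[f, 2], , drop = FALSE]
  c <- m$vertices[m$faces[f, 3], , drop = FALSE]
  a * u + b * v + c * w
}
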