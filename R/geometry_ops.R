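#' Closest surface points and distances
#'
#' Exact point-to-triangle minimum over all faces for each query point,
#' identical in value to an exhaustive scan (the scan is what the compiled
#' kernel performs, with ties broken toward the lowest face index).
#'
#' @param points query point (length 3) or n x 3 matrix (mm).
#' @param m a `triangle_mesh`.
#' @return for `closest_points`: a list with `distance` (n), `closest`
#'   (n x 3), `face` (n, 1-based) and `bary` (n x 3 barycentric
#'   coordinates). `closest_point_on_mesh` is the single-point convenience
#'   form returning `point` and `distance`.
#' @export
closest_points <- function(points, m) {
  .assert_mesh(m)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be 3D")
  if (nrow(points) == 0L) stop("empty point set")
  cpp_closest_points(points, m$vertices, m$faces)
}

#' @rdname closest_points
#' @param p a single 3D point.
#' @export
closest_point_on_mesh <- function(p, m) {
  res <- closest_points(matrix(p, ncol = 3), m)
  list(point = drop(res$closest), distance = res$distance[1],
       face = res$face[1], bary = drop(res$bary))
}

#' Least-squares similarity alignment of corresponded point sets
#'
#' Kabsch/Umeyama solution for the rotation (+ translation, + optional
#' isotropic scale) minimizing the sum of squared distances between
#' corresponded points. Reflections are excluded.
#'
#' @param source,target equal-length corresponded n x 3 matrices, n >= 3,
#'   not collinear.
#' @param allow_scale estimate an isotropic scale (default FALSE: rigid).
#' @return a transform: list with `rotation` (3 x 3), `translation`
#'   (length 3), `scale`, and `rmsd` of the aligned pair. Apply with
#'   [apply_transform()]; the mapping is
#'   `target ~ scale * rotation %*% source + translation`.
#' @export
procrustes_align <- function(source, target, allow_scale = FALSE) {
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target)))
    stop("source and target must be corresponded (equal dimensions)")
  if (nrow(source) < 3L) stop("need at least 3 points")
  mu_s <- colMeans(source); mu_t <- colMeans(target)
  X <- sweep(source, 2, mu_s); Y <- sweep(target, 2, mu_t)
  if (min(svd(X)$d[2], svd(Y)$d[2]) < 1e-9 * max(svd(X)$d[1], 1e-300))
    stop("degenerate (collinear) point configuration")
  S <- crossprod(X, Y)
  sv <- svd(S)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  s <- 1
  if (allow_scale) {
    s <- sum(sv$d * c(1, 1, d)) / sum(X^2)
  }
  t_vec <- mu_t - s * as.vector(R %*% mu_s)
  aligned <- s * X %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Y)^2)))
  list(rotation = R, translation = t_vec, scale = s, rmsd = rmsd)
}

#' Apply a similarity transform to points
#' @param points n x 3 matrix or length-3 vector.
#' @param transform as returned by [procrustes_align()].
#' @return transformed points, same shape.
#' @export
apply_transform <- function(points, transform) {
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, ncol = 3)
  out <- transform$scale * points %*% t(transform$rotation)
  out <- sweep(out, 2, transform$translation, "+")
  if (vec) drop(out) else out
}

#' Invert a similarity transform
#' @param transform as returned by [procrustes_align()].
#' @return the inverse transform.
#' @export
invert_transform <- function(transform) {
  Rin <- t(transform$rotation)
  s <- 1 / transform$scale
  list(rotation = Rin, translation = -s * as.vector(Rin %*% transform$translation),
       scale = s, rmsd = NA_real_)
}

identity_transform <- function() {
  list(rotation = diag(3), translation = c(0, 0, 0), scale = 1, rmsd = 0)
}

#' Rotation matrix about a coordinate axis
#' @param axis "x", "y" or "z".
#' @param angle angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
axis_rotation <- function(axis, angle) {
  c_ <- cos(angle); s_ <- sin(angle)
  switch(axis,
    x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
    y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
    z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)),
    stop("axis must be x, y or z"))
}
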