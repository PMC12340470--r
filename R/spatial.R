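#' Per-vertex scalar map on a reference surface
#'
#' @param reference a `triangle_mesh` (typically the model mean shape).
#' @param per_vertex_value numeric, one value per vertex (NA = unobserved).
#' @param kind "density" (points per mm^2) or "asd" (mm).
#' @return a `surface_map`.
#' @export
surface_map <- function(reference, per_vertex_value,
                        kind = c("density", "asd")) {
  .assert_mesh(reference)
  kind <- match.arg(kind)
  if (length(per_vertex_value) != nrow(reference$vertices))
    stop("value count must equal vertex count")
  structure(list(reference = reference,
                 per_vertex_value = as.numeric(per_vertex_value),
                 kind = kind),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  v <- x$per_vertex_value
  cat(sprintf("surface_map (%s): %d vertices, range %.3g-%.3g\n",
              x$kind, length(v), min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' Write a surface map as per-vertex PLY property plus CSV
#' @param map a `surface_map`.
#' @param ply_path,csv_path output paths (either may be NULL to skip).
#' @return invisibly, the paths written.
#' @export
write_surface_map <- function(map, ply_path = NULL, csv_path = NULL) {
  if (!is.null(ply_path))
    write_mesh(map$reference, ply_path, "ply",
               vertex_scalar = ifelse(is.na(map$per_vertex_value), -1,
                                      map$per_vertex_value))
  if (!is.null(csv_path))
    utils::write.csv(data.frame(vertex_id = seq_along(map$per_vertex_value),
                                value = map$per_vertex_value),
                     csv_path, row.names = FALSE)
  invisible(c(ply = ply_path, csv = csv_path))
}

#' Register an annotation onto the reference (mean) shape
#'
#' Landmark-initialized rigid alignment of the annotation onto the model
#' mean shape, followed by mapping each point to its closest
#' reference-surface location (with the barycentric record retained).
#' Rigid motion of the whole annotation is absorbed by the registration.
#'
#' @param a a `point_annotation`.
#' @param ssm a `statistical_shape_model`.
#' @param allow_scale estimate isotropic scale from the landmarks (default
#'   TRUE: glands of different sizes are normalized onto the common
#'   reference).
#' @return list: `mapped` (points on the reference surface), `aligned`
#'   (rigidly aligned raw points), `distance` (residual to surface, mm),
#'   `face`, `bary`, `transform`.
#' @export
register_annotation_to_reference <- function(a, ssm, allow_scale = TRUE) {
  .assert_annotation(a)
  .assert_ssm(ssm)
  ref <- ssm$mean_shape
  tr <- procrustes_align(a$landmarks, mesh_landmarks(ref),
                         allow_scale = allow_scale)
  aligned <- apply_transform(a$points, tr)
  cp <- closest_points(aligned, ref)
  list(mapped = cp$closest, aligned = aligned, distance = cp$distance,
       face = cp$face, bary = cp$bary, transform = tr)
}

.gauss_kernel_matrix <- function(V, pts, bandwidth) {
  # vertices x points kernel weights
  d2 <- outer(rowSums(V^2), rowSums(pts^2), "+") - 2 * V %*% t(pts)
  exp(-pmax(d2, 0) / (2 * bandwidth^2))
}

#' Kernel density of mapped points on the reference surface
#'
#' Per-vertex Gaussian-kernel density (Euclidean kernel; the prostate-scale
#' surface is near-convex, so the Euclidean distance is a close proxy for
#' the geodesic one at the default 5 mm bandwidth). The map is normalized
#' so that the surface integral (sum of density times vertex area) equals
#' the number of points.
#'
#' @param reference a `triangle_mesh`.
#' @param mapped_points n x 3 matrix of points on (or near) the surface.
#' @param bandwidth_mm kernel bandwidth (mm), > 0.
#' @return a `surface_map` of kind "density".
#' @export
surface_density_map <- function(reference, mapped_points, bandwidth_mm = 5) {
  .assert_mesh(reference)
  if (bandwidth_mm <= 0) stop("bandwidth must be positive")
  mapped_points <- as.matrix(mapped_points)
  if (!nrow(mapped_points)) stop("no points")
  Km <- .gauss_kernel_matrix(reference$vertices, mapped_points, bandwidth_mm)
  raw <- rowSums(Km)
  va <- vertex_areas(reference)
  dens <- raw * nrow(mapped_points) / sum(raw * va)
  surface_map(reference, dens, "density")
}

#' Kernel-weighted mean of per-point values on the reference surface
#'
#' Used to map per-point ASD values onto the average shape; vertices whose
#' total kernel weight falls below `weight_floor` carry NA (unobserved).
#'
#' @param reference a `triangle_mesh`.
#' @param mapped_points n x 3 matrix on the surface.
#' @param values numeric vector paired with the points (e.g., per-point
#'   distances to the semi-automatic consensus, mm).
#' @param bandwidth_mm kernel bandwidth (mm).
#' @param weight_floor minimum total kernel weight for a vertex to be
#'   considered observed.
#' @return a `surface_map` of kind "asd".
#' @export
surface_asd_map <- function(reference, mapped_points, values,
                            bandwidth_mm = 5, weight_floor = 1e-4) {
  .assert_mesh(reference)
  mapped_points <- as.matrix(mapped_points)
  if (nrow(mapped_points) != length(values))
    stop("values must be paired with points")
  if (!nrow(mapped_points)) stop("no points")
  Km <- .gauss_kernel_matrix(reference$vertices, mapped_points, bandwidth_mm)
  tot <- rowSums(Km)
  val <- as.vector(Km %*% values) / tot
  val[tot < weight_floor] <- NA_real_
  surface_map(reference, val, "asd")
}

#' Apex/base geodesic-cap vertex sets of a reference shape
#'
#' Region-level summaries ("apex", "base") use caps holding a fixed
#' fraction of the surface area around the two poles, grown by Euclidean
#' distance from the pole landmark.
#' @param m a `triangle_mesh` in the model frame.
#' @param area_fraction cap size as a fraction of total surface area.
#' @return list with integer vertex index vectors `apex` and `base`.
#' @export
pole_caps <- function(m, area_fraction = 0.25) {
  .assert_mesh(m)
  lm <- mesh_landmarks(m)
  va <- vertex_areas(m)
  total <- sum(va)
  cap <- function(pole) {
    d <- sqrt(rowSums(sweep(m$vertices, 2, pole)^2))
    ord <- order(d)
    keep <- ord[cumsum(va[ord]) <= area_fraction * total]
    sort(keep)
  }
  list(apex = cap(lm["apex", ]), base = cap(lm["base", ]))
}
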