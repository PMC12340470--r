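#' Average surface distance from points to a mesh (mm)
#'
#' Arithmetic mean over the points of the unsigned closest distance to the
#' surface: the primary variability metric for manual segmentations, where
#' the only observable is the expert's point cloud.
#'
#' @param points n x 3 matrix (mm), n >= 1.
#' @param m a `triangle_mesh`.
#' @return mean distance in mm.
#' @export
asd_points_to_mesh <- function(points, m) {
  mean(closest_points(points, m)$distance)
}

#' Symmetric average surface distance between two meshes (mm)
#'
#' Mean of the two directed means of vertex-to-surface distances. The
#' directed variants are available through `directed = "ab"` / `"ba"` for
#' diagnostics; the default symmetric form makes pairwise expert tables
#' order-free.
#'
#' @param a,b `triangle_mesh` objects.
#' @param directed "sym" (default), "ab" or "ba".
#' @return distance in mm.
#' @export
asd_mesh_to_mesh <- function(a, b, directed = c("sym", "ab", "ba")) {
  directed <- match.arg(directed)
  .assert_mesh(a); .assert_mesh(b)
  d_ab <- function() mean(closest_points(a$vertices, b)$distance)
  d_ba <- function() mean(closest_points(b$vertices, a)$distance)
  switch(directed,
         ab = d_ab(), ba = d_ba(),
         sym = (d_ab() + d_ba()) / 2)
}

#' Symmetric Hausdorff distance between two meshes (mm)
#'
#' Maximum over both directed maxima of vertex-to-opposing-surface
#' distances; captures the worst local disagreement between two
#' segmentations.
#' @inheritParams asd_mesh_to_mesh
#' @return distance in mm.
#' @export
hausdorff <- function(a, b) {
  .assert_mesh(a); .assert_mesh(b)
  max(max(closest_points(a$vertices, b)$distance),
      max(closest_points(b$vertices, a)$distance))
}

#' Volumetric Dice similarity coefficient of two watertight meshes
#'
#' 2|A intersect B| / (|A| + |B|) computed on the common voxelization of
#' both interiors over the union bounding box. The default voxel edge of
#' 0.46 mm matches the in-plane pixel size of the 3D TRUS acquisitions
#' whose segmentations this package analyses.
#'
#' @param a,b watertight `triangle_mesh` objects.
#' @param voxel_mm voxel edge length (mm), > 0.
#' @return Dice coefficient in [0, 1].
#' @export
dice_meshes <- function(a, b, voxel_mm = 0.46) {
  .assert_mesh(a); .assert_mesh(b)
  if (voxel_mm <= 0) stop("voxel_mm must be positive")
  for (nm in c("a", "b")) {
    m <- get(nm)
    if (!isTRUE(as.logical(is_watertight(m))))
      stop("mesh '", nm, "' is not watertight; Dice is undefined")
  }
  lo <- pmin(apply(a$vertices, 2, min), apply(b$vertices, 2, min)) - voxel_mm
  hi <- pmax(apply(a$vertices, 2, max), apply(b$vertices, 2, max)) + voxel_mm
  dims <- as.integer(ceiling((hi - lo) / voxel_mm))
  ina <- cpp_inside_mask(a$vertices, a$faces, lo, voxel_mm, dims)
  inb <- cpp_inside_mask(b$vertices, b$faces, lo, voxel_mm, dims)
  na <- sum(ina); nb <- sum(inb)
  if (na + nb == 0) stop("both meshes voxelize to empty interiors")
  2 * sum(ina & inb) / (na + nb)
}

#' All applicable metrics for a mesh pair
#'
#' Convenience record combining symmetric ASD, Hausdorff and (when both
#' meshes are watertight) Dice.
#' @inheritParams dice_meshes
#' @return named list `asd_mesh_mesh`, `hausdorff`, `dice` (NA when a mesh
#'   is not watertight).
#' @export
mesh_pair_metrics <- function(a, b, voxel_mm = 0.46) {
  dice <- if (isTRUE(as.logical(is_watertight(a))) &&
              isTRUE(as.logical(is_watertight(b))))
    dice_meshes(a, b, voxel_mm) else NA_real_
  list(asd_mesh_mesh = asd_mesh_to_mesh(a, b),
       hausdorff = hausdorff(a, b),
       dice = dice)
}
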