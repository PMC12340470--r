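#' Read a triangle mesh from PLY (ASCII), STL (ASCII) or OBJ
#'
#' PLY ASCII is the canonical interchange format; STL and OBJ are supported
#' without per-vertex metadata. Degenerate (zero-area) faces are dropped
#' with a message rather than rejecting the mesh. Non-manifold input is
#' flagged with a warning, not an error: only the volumetric Dice requires
#' watertightness.
#'
#' @param path file path.
#' @param format one of "ply", "stl", "obj"; inferred from the extension
#'   when missing.
#' @param topology_id optional correspondence tag to attach.
#' @return a `triangle_mesh` (coordinates are kept as-is and interpreted
#'   as mm).
#' @export
read_mesh <- function(path, format = NULL, topology_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- .mesh_format(path, format)
  m <- switch(format,
    ply = .read_ply(path),
    stl = .read_stl(path),
    obj = .read_obj(path))
  m$topology_id <- topology_id
  chk <- cpp_edge_check(m$faces)
  if (!chk$watertight)
    warning("mesh is not watertight (", chk$n_bad_edges,
            " irregular edges); Dice will refuse it", call. = FALSE)
  m
}

#' Write a triangle mesh
#' @param m a `triangle_mesh`.
#' @param path output path.
#' @param format "ply" (ASCII, default), "stl" or "obj"; inferred from the
#'   extension when missing.
#' @param vertex_scalar optional per-vertex scalar written as a PLY
#'   `quality` property (PLY only), used for surface maps.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(m, path, format = NULL, vertex_scalar = NULL) {
  .assert_mesh(m)
  format <- .mesh_format(path, format)
  switch(format,
    ply = .write_ply(m, path, vertex_scalar),
    stl = .write_stl(m, path),
    obj = .write_obj(m, path))
  invisible(path)
}

.mesh_format <- function(path, format) {
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("ply", "stl", "obj"))
  format
}

.read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  end_hdr <- which(trimws(lines) == "end_header")[1]
  if (is.na(end_hdr)) stop("malformed PLY header (no end_header): ", path)
  hdr <- lines[seq_len(end_hdr)]
  if (!any(grepl("^format\\s+ascii", hdr)))
    stop("only ASCII PLY is supported: ", path)
  nv <- as.integer(sub("^element\\s+vertex\\s+", "",
                       grep("^element\\s+vertex\\s+\\d+", hdr, value = TRUE)[1]))
  nf <- as.integer(sub("^element\\s+face\\s+", "",
                       grep("^element\\s+face\\s+\\d+", hdr, value = TRUE)[1]))
  if (is.na(nv) || is.na(nf)) stop("malformed PLY header: ", path)
  body <- lines[-seq_len(end_hdr)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < nv + nf) stop("truncated PLY file: ", path)
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  V <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  F <- t(vapply(fparts, function(p) {
    n <- as.integer(p[1])
    if (is.na(n) || n != 3L) stop("only triangular faces are supported")
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  if (anyNA(V) || anyNA(F)) stop("unparseable PLY body: ", path)
  triangle_mesh(V, F)
}

.write_ply <- function(m, path, vertex_scalar = NULL) {
  nv <- nrow(m$vertices); nf <- nrow(m$faces)
  props <- c("property double x", "property double y", "property double z")
  if (!is.null(vertex_scalar)) {
    stopifnot(length(vertex_scalar) == nv)
    props <- c(props, "property double quality")
  }
  hdr <- c("ply", "format ascii 1.0",
           "comment units mm",
           paste("element vertex", nv), props,
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  vm <- m$vertices
  if (!is.null(vertex_scalar)) vm <- cbind(vm, vertex_scalar)
  vlines <- apply(vm, 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " "))
  flines <- apply(m$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(hdr, vlines, flines), path)
}

.read_stl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1]))
    stop("not an ASCII STL file: ", path)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl) || length(vl) %% 3L != 0L)
    stop("truncated or malformed STL file: ", path)
  if (!any(grepl("^\\s*endsolid", lines)))
    stop("truncated STL file (no endsolid): ", path)
  P <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(P)) stop("unparseable STL vertex line: ", path)
  # weld identical vertices back into a shared index space
  key <- apply(P, 1, function(r) paste(sprintf("%.9g", r), collapse = ","))
  uid <- match(key, unique(key))
  V <- P[!duplicated(key), , drop = FALSE]
  F <- matrix(uid, ncol = 3, byrow = TRUE)
  triangle_mesh(V, F)
}

.write_stl <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid mesh", con)
  V <- m$vertices; F <- m$faces
  for (f in seq_len(nrow(F))) {
    a <- V[F[f, 1], ]; b <- V[F[f, 2], ]; c <- V[F[f, 3], ]
    n <- .cross3(b - a, c - a)
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    writeLines(c(
      paste("facet normal", paste(sprintf("%.9g", n), collapse = " ")),
      "  outer loop",
      paste("    vertex", paste(sprintf("%.17g", a), collapse = " ")),
      paste("    vertex", paste(sprintf("%.17g", b), collapse = " ")),
      paste("    vertex", paste(sprintf("%.17g", c), collapse = " ")),
      "  endloop", "endfacet"), con)
  }
  writeLines("endsolid mesh", con)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("not a usable OBJ file: ", path)
  V <- t(vapply(strsplit(trimws(vl), "\\s+"),
                function(p) as.numeric(p[2:4]), numeric(3)))
  F <- t(vapply(strsplit(trimws(fl), "\\s+"), function(p) {
    if (length(p) != 4L) stop("only triangular OBJ faces are supported")
    as.integer(sub("/.*$", "", p[2:4]))
  }, integer(3)))
  if (anyNA(V) || anyNA(F)) stop("unparseable OBJ file: ", path)
  triangle_mesh(V, F)
}

.write_obj <- function(m, path) {
  vlines <- apply(m$vertices, 1, function(r)
    paste("v", paste(sprintf("%.17g", r), collapse = " ")))
  flines <- apply(m$faces, 1, function(r)
    paste("f", paste(r, collapse = " ")))
  writeLines(c("# units mm", vlines, flines), path)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
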