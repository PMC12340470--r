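#' Sparse expert point annotation
#'
#' One expert's point set for one prostate and session. Every annotation
#' carries exactly three labelled reference landmarks (apex, base,
#' posterior), matching the clinical protocol in which these three points
#' anchor every segmentation before contour points are placed.
#'
#' @param patient_id,expert_id identifiers (coerced to character).
#' @param method "manual" or "semi_auto".
#' @param session repeat index: 0 = first session, 1 = repeat ("bis").
#' @param points n x 3 matrix of contour points (mm).
#' @param landmarks 3 x 3 matrix with rownames "apex", "base", "posterior".
#' @param plane_tags optional character vector (one of "axial", "sagittal",
#'   "coronal") per contour point.
#' @return an object of class `point_annotation`.
#' @export
point_annotation <- function(patient_id, expert_id, method, session,
                             points, landmarks, plane_tags = NULL) {
  method <- match.arg(method, c("manual", "semi_auto"))
  points <- matrix(as.numeric(points), ncol = 3)
  landmarks <- as.matrix(landmarks)
  if (is.null(rownames(landmarks)) ||
      !setequal(rownames(landmarks), c("apex", "base", "posterior")))
    stop("landmarks must be exactly {apex, base, posterior}")
  if (anyDuplicated(rownames(landmarks)))
    stop("landmark labels must be unique")
  landmarks <- landmarks[c("apex", "base", "posterior"), , drop = FALSE]
  if (ncol(landmarks) != 3L) stop("landmarks must be 3D")
  if (!all(is.finite(points)) || !all(is.finite(landmarks)))
    stop("annotation coordinates must be finite")
  if (!is.null(plane_tags)) {
    if (length(plane_tags) != nrow(points))
      stop("plane_tags length must match points")
    if (!all(plane_tags %in% c("axial", "sagittal", "coronal")))
      stop("unknown plane tag")
  }
  dimnames(points) <- NULL
  colnames(landmarks) <- NULL
  structure(list(patient_id = as.character(patient_id),
                 expert_id = as.character(expert_id),
                 method = method, session = as.integer(session),
                 points = points, landmarks = landmarks,
                 plane_tags = if (!is.null(plane_tags))
                   unname(as.character(plane_tags))),
            class = "point_annotation")
}

#' @export
print.point_annotation <- function(x, ...) {
  cat("point_annotation: patient", x$patient_id, "expert", x$expert_id,
      sprintf("(%s, session %d), %d points + 3 landmarks\n",
              x$method, x$session, nrow(x$points)))
  invisible(x)
}

.assert_annotation <- function(a, min_points = 0L) {
  if (!inherits(a, "point_annotation")) stop("not a point_annotation")
  if (nrow(a$points) < min_points)
    stop("annotation has ", nrow(a$points), " points; need >= ", min_points)
  invisible(a)
}

#' All attraction points of an annotation (contour points + landmarks)
#' @param a a `point_annotation`.
#' @return (n+3) x 3 matrix.
#' @export
annotation_points <- function(a) {
  .assert_annotation(a)
  rbind(a$points, unname(a$landmarks))
}

#' Write / read an annotation as CSV
#'
#' One point per row with header
#' `patient_id,expert_id,method,session,label,x_mm,y_mm,z_mm,plane`.
#' Landmark rows carry their label; contour rows are labelled "point".
#' The round trip is lossless.
#'
#' @param a a `point_annotation`.
#' @param path file path.
#' @return `path` invisibly (write) or a `point_annotation` (read).
#' @export
write_annotation_csv <- function(a, path) {
  .assert_annotation(a)
  pl <- if (is.null(a$plane_tags)) rep("", nrow(a$points)) else a$plane_tags
  df <- data.frame(
    patient_id = a$patient_id, expert_id = a$expert_id,
    method = a$method, session = a$session,
    label = c(rep("point", nrow(a$points)), rownames(a$landmarks)),
    x_mm = c(a$points[, 1], a$landmarks[, 1]),
    y_mm = c(a$points[, 2], a$landmarks[, 2]),
    z_mm = c(a$points[, 3], a$landmarks[, 3]),
    plane = c(pl, rep("", 3)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       expert_id = "character"))
  need <- c("patient_id", "expert_id", "method", "session",
            "label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("annotation CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  .annotation_from_df(df)
}

.annotation_from_df <- function(df) {
  lm_rows <- df$label %in% c("apex", "base", "posterior")
  lms <- df[lm_rows, , drop = FALSE]
  if (!setequal(lms$label, c("apex", "base", "posterior")))
    stop("annotation is missing landmark row(s): ",
         paste(setdiff(c("apex", "base", "posterior"), lms$label),
               collapse = ", "))
  landmarks <- as.matrix(lms[, c("x_mm", "y_mm", "z_mm")])
  rownames(landmarks) <- lms$label
  pts <- df[!lm_rows, , drop = FALSE]
  plane <- NULL
  if ("plane" %in% names(df) && nrow(pts) && any(nzchar(pts$plane)))
    plane <- ifelse(nzchar(pts$plane), pts$plane, "axial")
  point_annotation(df$patient_id[1], df$expert_id[1], df$method[1],
                   df$session[1],
                   as.matrix(pts[, c("x_mm", "y_mm", "z_mm")]),
                   landmarks, plane)
}

#' Write / read an annotation as JSON
#'
#' JSON mirror of the CSV layout. Unknown top-level keys in the input are
#' ignored with a message.
#' @inheritParams write_annotation_csv
#' @export
write_annotation_json <- function(a, path) {
  .assert_annotation(a)
  obj <- list(patient_id = a$patient_id, expert_id = a$expert_id,
              method = a$method, session = a$session,
              points = a$points,
              landmarks = lapply(seq_len(3), function(i)
                unname(a$landmarks[i, ])),
              plane_tags = a$plane_tags)
  names(obj$landmarks) <- rownames(a$landmarks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
read_annotation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("patient_id", "expert_id", "method", "session",
            "points", "landmarks")
  extra <- setdiff(names(obj), c(need, "plane_tags"))
  if (length(extra))
    message("ignoring unknown annotation keys: ",
            paste(extra, collapse = ", "))
  if (!all(need %in% names(obj)))
    stop("annotation JSON missing keys: ",
         paste(setdiff(need, names(obj)), collapse = ", "))
  lmn <- names(obj$landmarks)
  landmarks <- do.call(rbind, lapply(obj$landmarks,
                                     function(r) as.numeric(unlist(r))))
  rownames(landmarks) <- lmn
  pts <- obj$points
  if (is.list(pts) && !is.matrix(pts))
    pts <- do.call(rbind, lapply(pts, function(r) as.numeric(unlist(r))))
  if (is.null(pts) || !length(pts)) pts <- matrix(numeric(0), ncol = 3)
  tags <- obj$plane_tags
  if (is.list(tags)) tags <- unlist(tags)
  if (!length(tags)) tags <- NULL
  point_annotation(obj$patient_id, obj$expert_id, obj$method, obj$session,
                   pts, landmarks, tags)
}
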