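#' Save / load a statistical shape model
#'
#' The model is stored as a small directory archive: the mean mesh as
#' ASCII PLY, the mode matrix as CSV (one column per mode) and a JSON
#' manifest with the eigenvalues and alignment convention.
#'
#' @param ssm a `statistical_shape_model`.
#' @param dir archive directory (created if needed).
#' @return `dir` (save) or the model (load), invisibly/visibly.
#' @export
save_ssm <- function(ssm, dir) {
  .assert_ssm(ssm)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(ssm$mean_shape, file.path(dir, "mean.ply"))
  utils::write.csv(as.data.frame(ssm$modes),
                   file.path(dir, "modes.csv"), row.names = FALSE)
  jsonlite::write_json(list(eigenvalues = ssm$eigenvalues,
                            n_train = ssm$n_train,
                            topology_id = ssm$mean_shape$topology_id,
                            alignment = ssm$alignment),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_ssm
#' @export
load_ssm <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  mean_mesh <- read_mesh(file.path(dir, "mean.ply"),
                         topology_id = man$topology_id)
  modes <- as.matrix(utils::read.csv(file.path(dir, "modes.csv")))
  dimnames(modes) <- NULL
  structure(list(mean_shape = mean_mesh, modes = modes,
                 eigenvalues = as.numeric(man$eigenvalues),
                 n_train = man$n_train, alignment = man$alignment),
            class = "statistical_shape_model")
}
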