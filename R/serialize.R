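#' Save a model to disk
#'
#' Models are plain R lists with class attributes, so they are stored via
#' \code{saveRDS}; all parameters round-trip exactly.  Gauge tags,
#' alphabets, estimator metadata and training-log attributes are preserved.
#'
#' @param model any model object of this package
#' @param path output path (conventionally \code{.rds})
#' @export
write_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved with \code{\link{write_model}}
#' @param path file path
#' @return the model object
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  readRDS(path)
}
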