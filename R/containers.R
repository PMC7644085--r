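# Self-describing plain-text (JSON) container for spectrograms and
# predictors, so intermediate arrays can be exchanged between pipeline
# stages and sessions.

#' Write a spectrogram to a JSON array container
#'
#' Stores `values`, `rate`, `band_centers` and `role` (plus `name` and
#' `l1_norms` for predictors) in a self-describing JSON file.
#'
#' @param spec A `spectrogram` or `predictor`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrogram <- function(spec, path) {
  stopifnot(inherits(spec, "spectrogram"))
  obj <- list(values = spec$values, rate = spec$rate,
              band_centers = spec$band_centers, role = spec$role)
  if (inherits(spec, "predictor")) {
    obj$name <- spec$name
    obj$l1_norms <- spec$l1_norms
    obj$zero_bands <- spec$zero_bands
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a spectrogram from a JSON array container
#'
#' @param path Path written by [write_spectrogram()].
#' @return A `spectrogram`, or a `predictor` if a name was stored.
#' @export
read_spectrogram <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- spectrogram(obj$values, obj$rate, obj$band_centers, obj$role)
  if (!is.null(obj$name)) {
    p <- predictor(spec, obj$name)
    if (!is.null(obj$l1_norms)) {
      p$l1_norms <- obj$l1_norms
      p$zero_bands <- obj$zero_bands
    }
    return(p)
  }
  spec
}
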