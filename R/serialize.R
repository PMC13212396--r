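#' Save and restore a fitted centile model
#'
#' Serializes a [fit_centiles()] object to a JSON document (covariate,
#' transform, basis description, coefficients, links, tau, range, fit
#' metadata). Numbers are written with 17 significant digits so the
#' save/load/predict round trip is bit-stable.
#'
#' @param fit A `centile_fit`.
#' @param path JSON file path.
#' @return `write_centile_model()` returns `path` invisibly;
#'   `read_centile_model()` the restored `centile_fit`.
#' @export
write_centile_model <- function(fit, path) {
  stopifnot(inherits(fit, "centile_fit"))
  doc <- unclass(fit)
  doc$package <- "hepanorm"
  doc$package_version <- as.character(utils::packageVersion("hepanorm"))
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_centile_model
#' @export
read_centile_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$package, "hepanorm")) {
    stop(path, " is not a serialized centile model")
  }
  fit <- doc[setdiff(names(doc), c("package", "package_version"))]
  fit$coef <- lapply(fit$coef, as.numeric)
  fit$lambda <- stats::setNames(as.numeric(fit$lambda), names(fit$lambda))
  fit$edf <- stats::setNames(as.numeric(fit$edf), names(fit$edf))
  fit$links <- unlist(fit$links)
  structure(fit, class = "centile_fit")
}
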