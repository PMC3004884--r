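#' Serialise a fitted discriminant model to JSON
#'
#' Writes the feature indices, projection matrix, 2D class means, class
#' order, eigenvalues and normalisation spec with full double precision,
#' so projections computed after reload reproduce the originals
#' bit-for-bit.
#'
#' @param model a [fisher_lda_fit()] model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lda_model <- function(model, path) {
  stopifnot(inherits(model, "fisher_lda"))
  payload <- list(
    type = "fisher_lda",
    features = model$features,
    projection = apply(model$projection, 1L, identity, simplify = FALSE),
    means2d = apply(model$means2d, 1L, identity, simplify = FALSE),
    classes = model$classes,
    eigenvalues = model$eigenvalues,
    normalisation = model$normalisation
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Load a serialised discriminant model
#'
#' @param path JSON file written by [write_lda_model()].
#' @return a `fisher_lda` model (scatter matrices are not persisted).
#' @export
read_lda_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$type) || x$type != "fisher_lda")
    .mrsdx_stop(sprintf("'%s' is not a serialised fisher_lda model", path),
                "mrsdx_format_error")
  proj <- do.call(rbind, if (is.list(x$projection)) x$projection
                  else apply(x$projection, 1L, identity, simplify = FALSE))
  means <- do.call(rbind, if (is.list(x$means2d)) x$means2d
                   else apply(x$means2d, 1L, identity, simplify = FALSE))
  rownames(means) <- x$classes
  structure(
    list(features = as.integer(x$features), projection = proj,
         means2d = means, classes = x$classes,
         eigenvalues = x$eigenvalues, Sw = NULL, Sb = NULL,
         normalisation = x$normalisation),
    class = "fisher_lda"
  )
}
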