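MODEL_SCHEMA_VERSION <- "fuzzytrack-model-1"

#' Save a correlation model to a JSON file
#'
#' All rule-base parameters and the normalization are written losslessly
#' (full double precision) to a versioned JSON schema, so that
#' `load_model(save_model(m))` predicts identically to `m`.
#'
#' @param model A `correlation_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "correlation_model"))
  rb_to_list <- function(rb) {
    list(centers = rb$centers, sigmas = rb$sigmas, coef = rb$coef,
         intercept = rb$intercept, output = rb$output,
         ls_warning = isTRUE(rb$ls_warning))
  }
  ns <- model$normalization
  payload <- list(
    schema = MODEL_SCHEMA_VERSION,
    model_kind = model$model_kind,
    rule_bases = lapply(model$rule_bases, rb_to_list),
    normalization = list(
      x_offset = ns$x_offset, x_scale = ns$x_scale,
      x_degenerate = ns$x_degenerate,
      y_offset = ns$y_offset, y_scale = ns$y_scale,
      y_degenerate = ns$y_degenerate),
    provenance = model$provenance
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                           matrix = "rowmajor")
  writeLines(json, path)
  invisible(path)
}

#' Load a correlation model saved by [save_model()]
#'
#' @param path File path.
#' @return A `correlation_model`.
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::fromJSON(paste(readLines(path, warn = FALSE), collapse = "\n"),
                       simplifyDataFrame = FALSE, simplifyMatrix = TRUE),
    error = function(e) {
      stop("cannot parse model file ", path, ": ", conditionMessage(e))
    })
  if (is.null(payload$schema) || !identical(payload$schema, MODEL_SCHEMA_VERSION)) {
    stop("model schema version mismatch in ", path, ": expected '",
         MODEL_SCHEMA_VERSION, "', got '", payload$schema %||% "none", "'")
  }
  rb_from_list <- function(l) {
    rb <- rule_base(as.matrix(l$centers), as.matrix(l$sigmas),
                    coef = as.matrix(l$coef), intercept = l$intercept,
                    output = l$output)
    rb$ls_warning <- isTRUE(l$ls_warning)
    rb
  }
  rbs <- lapply(payload$rule_bases, rb_from_list)
  ns <- payload$normalization
  spec <- structure(list(
    x_offset = as.numeric(ns$x_offset), x_scale = as.numeric(ns$x_scale),
    x_degenerate = as.logical(ns$x_degenerate),
    y_offset = as.numeric(ns$y_offset), y_scale = as.numeric(ns$y_scale),
    y_degenerate = as.logical(ns$y_degenerate)), class = "norm_spec")
  correlation_model(payload$model_kind, rbs, spec,
                    provenance = payload$provenance)
}
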