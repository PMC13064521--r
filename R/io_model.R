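# On-disk model format: a versioned, self-describing JSON container.

MODEL_FORMAT_VERSION <- 1L

#' Save a boosting model to disk
#'
#' JSON container with a format version and full-precision numbers; identical
#' models serialize to identical bytes.
#'
#' @param model An `ebm_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ebm_model"))
  if (length(model$feature_names) == 0) stop("cannot save an empty-feature model")
  payload <- list(
    format = "somagraph-ebm",
    format_version = MODEL_FORMAT_VERSION,
    intercept = model$intercept,
    feature_names = model$feature_names,
    bin_edges = model$bin_edges,
    shapes = model$shapes,
    thresholds = as.list(model$thresholds),
    metadata = model$metadata)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Load a boosting model from disk
#'
#' @param path Path written by [save_model()].
#' @return An `ebm_model`; `save_model` then `load_model` is the identity on
#'   intercept, bin edges, shape values, feature names and thresholds.
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop("cannot parse model file: ",
                                               conditionMessage(e)))
  if (!identical(payload$format, "somagraph-ebm")) {
    stop("not a somagraph model file")
  }
  if (!identical(as.integer(payload$format_version), MODEL_FORMAT_VERSION)) {
    stop("unsupported model format version: ", payload$format_version)
  }
  edges <- payload$bin_edges
  shapes <- payload$shapes
  # jsonlite may simplify lists of equal-length vectors to matrices
  as_list <- function(x, nms) {
    if (is.matrix(x)) x <- lapply(seq_len(nrow(x)), function(i) x[i, ])
    if (is.data.frame(x)) x <- as.list(x)
    x <- lapply(x, as.numeric)
    names(x) <- nms
    x
  }
  model <- list(version = 1L, intercept = as.numeric(payload$intercept),
                feature_names = as.character(payload$feature_names),
                bin_edges = as_list(edges, payload$feature_names),
                shapes = as_list(shapes, payload$feature_names),
                thresholds = unlist(payload$thresholds),
                metadata = payload$metadata,
                loss_trace = NULL)
  class(model) <- "ebm_model"
  model
}
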