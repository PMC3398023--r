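#' Serialize a timing model to JSON
#'
#' Writes a single JSON document \code{\{K, M, means, global_weights,
#' independent_vars, jitter_vars, labels, metadata\{seed, version\}\}} with
#' the weight matrix stored row-major and all numbers at full precision, so
#' a write/read round trip reproduces the model exactly.
#'
#' @param model a [timing_model()].
#' @param path output path.
#' @param seed optional seed to record in the metadata.
#' @return the path, invisibly.
#' @export
write_timing_model <- function(model, path, seed = NULL) {
  stopifnot(inherits(model, "timing_model"))
  doc <- list(
    K = model$n_intervals, M = model$n_global,
    means = model$means,
    global_weights = unname(model$global_weights),
    independent_vars = model$independent_vars,
    jitter_vars = model$jitter_vars,
    labels = model$labels,
    metadata = list(seed = seed,
                    version = as.character(utils::packageVersion(
                      "timefactor"))))
  write_atomic(path, function(tmp)
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = I(17),
                         null = "null"))
  invisible(path)
}

#' Read a timing model from JSON
#'
#' @param path path to a JSON document written by [write_timing_model()].
#' @return a [timing_model()]; the recorded metadata is attached as the
#'   \code{"metadata"} attribute.
#' @export
read_timing_model <- function(path) {
  doc <- jsonlite::fromJSON(path)
  W <- matrix(as.numeric(t(as.matrix(doc$global_weights))),
              nrow = doc$K, ncol = doc$M, byrow = TRUE)
  ## fromJSON already returns nested arrays as a row-major matrix; the
  ## explicit reshape above guards the M = 1 column/vector edge cases
  if (is.matrix(doc$global_weights) &&
      all(dim(doc$global_weights) == c(doc$K, doc$M)))
    W <- matrix(as.numeric(doc$global_weights), doc$K, doc$M)
  model <- timing_model(W, doc$independent_vars, doc$jitter_vars,
                        means = doc$means,
                        labels = if (!is.null(doc$labels) &&
                                     length(doc$labels)) doc$labels)
  attr(model, "metadata") <- doc$metadata
  model
}
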