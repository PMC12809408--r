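MODEL_SCHEMA_VERSION <- "senoscope-sid-model/1"

#' Save a trained SID model
#'
#' Serialises the model to a versioned, human-readable JSON document so that
#' feature lists and the calibration parameters (alpha, beta) are auditable.
#' Doubles are written at full precision; a save/load round trip scores any
#' input bit-identically.
#'
#' @param model a `sid_model` from [train_sid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_sid_model <- function(model, path) {
  stopifnot(inherits(model, "sid_model"))
  doc <- list(
    schema = MODEL_SCHEMA_VERSION,
    mode_id = model$mode_id,
    feature_genes = model$feature_genes,
    weights = num_to_hex(model$weights),
    bias = num_to_hex(model$bias),
    alpha = num_to_hex(model$alpha),
    beta = num_to_hex(model$beta),
    threshold = num_to_hex(model$threshold),
    train_meta = model$train_meta,
    elimination_order = model$elimination_order
  )
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), path)
  invisible(path)
}

#' Load a SID model saved with [save_sid_model()]
#'
#' @param path model file.
#' @return a `sid_model`.
#' @export
load_sid_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("model file not found: %s", path))
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE),
    error = function(e) stop(sprintf("corrupted model file %s: %s",
                                     path, conditionMessage(e)))
  )
  if (is.null(doc$schema) || !identical(doc$schema, MODEL_SCHEMA_VERSION)) {
    stop(sprintf("unknown model schema version '%s' (expected '%s')",
                 if (is.null(doc$schema)) "<none>" else doc$schema,
                 MODEL_SCHEMA_VERSION))
  }
  required <- c("feature_genes", "weights", "bias", "alpha", "beta")
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0L) {
    stop(sprintf("model file %s is missing fields: %s", path,
                 paste(missing, collapse = ", ")))
  }
  w <- hex_to_num(doc$weights)
  names(w) <- doc$feature_genes
  model <- new_sid_model(
    mode_id = as.integer(doc$mode_id),
    feature_genes = as.character(doc$feature_genes),
    weights = w,
    bias = hex_to_num(doc$bias),
    alpha = hex_to_num(doc$alpha),
    beta = hex_to_num(doc$beta),
    threshold = hex_to_num(doc$threshold),
    train_meta = doc$train_meta,
    elimination_order = as.character(doc$elimination_order)
  )
  model
}

# Doubles are stored as C99 hex-float strings ("%a") alongside nothing else;
# this guarantees exact binary round-tripping while staying plain text.
num_to_hex <- function(x) sprintf("%a", as.numeric(x))

hex_to_num <- function(s) {
  out <- suppressWarnings(as.numeric(s))
  if (any(is.na(out))) {
    stop("corrupted numeric payload in model file")
  }
  out
}
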