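# Text persistence of trained models. The container is self-describing JSON
# with explicit shapes; all numeric payloads are encoded as "%.17g" strings,
# which round-trip IEEE doubles bit-exactly (17 significant digits are
# sufficient and strtod parsing is correctly rounded). The contract:
# write -> read -> write is byte-identical, and a reloaded model estimates
# bitwise identically to the in-memory one.

MODEL_FORMAT <- "sgrnet-model"
MODEL_VERSION <- 1L

enc_num <- function(x) sprintf("%.17g", as.numeric(x))
dec_num <- function(s) as.numeric(s)

enc_matrix <- function(m) {
  list(nrow = nrow(m), ncol = ncol(m), data = enc_num(as.vector(m)))
}
dec_matrix <- function(l) {
  matrix(dec_num(l$data), nrow = l$nrow, ncol = l$ncol)
}

#' Write a trained model to a text file
#'
#' Serializes an `sgr_model` — reservoir matrices, readout weights, input
#' set, normalization ranges, configuration and provenance — to a
#' self-describing JSON container with full double precision (numeric
#' payloads are stored as 17-significant-digit strings and round-trip
#' bit-exactly).
#'
#' @param model An `sgr_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_model()]
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "sgr_model"))
  net <- model$network
  obj <- list(
    format = MODEL_FORMAT,
    version = MODEL_VERSION,
    network = list(
      n_neurons = net$n_neurons, n_inputs = net$n_inputs,
      time_scale = enc_num(net$time_scale), bias = enc_num(net$bias),
      spectral_radius = enc_num(net$spectral_radius),
      input_scale = enc_num(net$input_scale),
      sparsity = enc_num(net$sparsity), seed = net$seed,
      w_in = enc_matrix(net$w_in), w_sys = enc_matrix(net$w_sys)
    ),
    w_out = enc_num(model$w_out),
    features = as.list(model$features),
    feature_ranges = lapply(model$feature_ranges, function(r)
      list(name = r$name, min = enc_num(r$min), max = enc_num(r$max))),
    sgr_range = list(name = model$sgr_range$name,
                     min = enc_num(model$sgr_range$min),
                     max = enc_num(model$sgr_range$max)),
    config = list(passes = model$config$passes,
                  forgetting = enc_num(model$config$forgetting),
                  beta = enc_num(model$config$beta),
                  seed = model$config$seed),
    provenance = list(datasets = as.list(model$provenance$datasets),
                      n_train = model$provenance$n_train)
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a trained model from a text file
#'
#' Inverse of [write_model()]. A file whose `format`/`version` fields do not
#' match this package's model container is rejected with an explicit
#' unsupported-version error; malformed or truncated files give a parse
#' error.
#'
#' @param path Path to a model file written by [write_model()].
#' @return An `sgr_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop_validation("model file not found: %s", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop_validation("failed to parse model file '%s': %s",
                                    path, conditionMessage(e))
                  })
  if (!identical(obj$format, MODEL_FORMAT)) {
    stop_validation("'%s' is not a %s file", path, MODEL_FORMAT)
  }
  if (!identical(as.integer(obj$version), MODEL_VERSION)) {
    stop_validation("unsupported model file version %s (this build reads version %d)",
                    as.character(obj$version), MODEL_VERSION)
  }
  nn <- obj$network
  net <- structure(list(
    n_neurons = as.integer(nn$n_neurons), n_inputs = as.integer(nn$n_inputs),
    time_scale = dec_num(nn$time_scale), bias = dec_num(nn$bias),
    spectral_radius = dec_num(nn$spectral_radius),
    input_scale = dec_num(nn$input_scale), sparsity = dec_num(nn$sparsity),
    seed = as.integer(nn$seed),
    w_in = dec_matrix(nn$w_in), w_sys = dec_matrix(nn$w_sys)
  ), class = "reservoir_network")
  features <- as.character(unlist(obj$features))
  ranges <- lapply(seq_along(features), function(i) {
    r <- if (is.data.frame(obj$feature_ranges)) obj$feature_ranges[i, ]
         else obj$feature_ranges[[i]]
    feature_range(as.character(r$name), dec_num(r$min), dec_num(r$max))
  })
  names(ranges) <- features
  structure(list(
    network = net,
    w_out = dec_num(obj$w_out),
    features = features,
    feature_ranges = ranges,
    sgr_range = feature_range("sgr", dec_num(obj$sgr_range$min),
                              dec_num(obj$sgr_range$max)),
    config = list(passes = as.integer(obj$config$passes),
                  forgetting = dec_num(obj$config$forgetting),
                  beta = dec_num(obj$config$beta),
                  seed = as.integer(obj$config$seed)),
    provenance = list(datasets = as.character(unlist(obj$provenance$datasets)),
                      n_train = as.integer(obj$provenance$n_train))
  ), class = "sgr_model")
}
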