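# Training, estimation, splitting, evaluation and the seven-way input
# ablation — the experimental machinery around the reservoir.

#' The seven input sets
#'
#' All non-empty subsets of \{weight, T/C ratio, CF\}, in the conventional
#' order: the three single inputs, the three pairs, and the full three-input
#' combination. Ablation over these sets asks which biological factors carry
#' the SGR signal.
#'
#' @return A named list of character vectors of feature column names.
#' @export
input_sets <- function() {
  list("W"        = "weight_g",
       "T/C"      = "tc_ratio",
       "CF"       = "cf",
       "W+T/C"    = c("weight_g", "tc_ratio"),
       "T/C+CF"   = c("tc_ratio", "cf"),
       "W+CF"     = c("weight_g", "cf"),
       "W+T/C+CF" = c("weight_g", "tc_ratio", "cf"))
}

#' Train an SGR estimation model
#'
#' Fits the linear readout of a fixed random reservoir to the normalized SGR
#' of a fish dataset, online: records are presented in stored dataset order,
#' the reservoir state is carried across records within a pass (reset to
#' zero between passes), and the readout weights are updated by recursive
#' least squares at each input-target pair. Normalization ranges for the
#' input features and for SGR are computed from the training records only
#' and stored with the model; they are what later converts normalized
#' network outputs back to % day^-1.
#'
#' @param data A `fish_dataset` (or coercible data frame) whose records all
#'   carry the requested features and `sgr`; at least 2 records.
#' @param features Character vector of input features, a subset of
#'   `c("weight_g", "tc_ratio", "cf")`. Default: all three (the combination
#'   found to give the lowest estimation error).
#' @param n_neurons,time_scale,bias,spectral_radius,input_scale,sparsity
#'   Reservoir settings, see [reservoir_network()]. `time_scale` defaults to
#'   1 (no leak): per-fish records are exchangeable, so carrying a leaky
#'   memory of the previous fish adds noise rather than signal; set 0.3 to
#'   reproduce the temporally-smoothed convention sometimes used for
#'   within-experiment series.
#' @param passes Number of passes over the data; default 1 (strict online
#'   training).
#' @param forgetting,beta RLS settings, see [rls_state()].
#' @param seed Seed for the reservoir construction; the whole function is
#'   deterministic given `(data, config, seed)`.
#' @return An object of class `sgr_model`: the network, trained readout
#'   `w_out`, feature ranges, SGR range, and provenance.
#' @examples
#' d <- generate_dataset(stage_preset("adult"), n = 60, seed = 1)
#' m <- train_model(d, seed = 1)
#' @export
train_model <- function(data, features = c("weight_g", "tc_ratio", "cf"),
                        n_neurons = 50, time_scale = 1, passes = 1,
                        forgetting = 0.99, beta = 1e-4, bias = 0.001,
                        spectral_radius = 0.9, input_scale = 0.1,
                        sparsity = 0.5, seed = 1) {
  data <- as_fish_dataset(data)
  if (nrow(data) < 2) {
    stop_validation("training needs at least 2 records (got %d)", nrow(data))
  }
  if (passes < 1) stop_validation("passes must be >= 1")
  check_features(data, features, need_sgr = TRUE)

  ranges <- lapply(features, function(f) range_of(data[[f]], f))
  names(ranges) <- features
  sgr_range <- range_of(data$sgr, "sgr")
  for (r in ranges) check_nondegenerate(r)
  check_nondegenerate(sgr_range)

  net <- reservoir_network(n_inputs = length(features), n_neurons = n_neurons,
                           time_scale = time_scale, bias = bias,
                           spectral_radius = spectral_radius,
                           input_scale = input_scale, sparsity = sparsity,
                           seed = seed)
  u <- vapply(features, function(f) normalize_feature(data[[f]], ranges[[f]]),
              numeric(nrow(data)))
  u <- matrix(u, ncol = length(features))
  d <- normalize_feature(data$sgr, sgr_range)

  rls <- rls_state(n_neurons, forgetting = forgetting, beta = beta)
  for (p in seq_len(passes)) {
    x <- numeric(net$n_neurons)
    for (t in seq_len(nrow(u))) {
      x <- reservoir_step(net, x, u[t, ])
      rls <- rls_update(rls, x, d[t])
    }
  }

  structure(list(
    network = net,
    w_out = rls$w_out,
    features = features,
    feature_ranges = ranges,
    sgr_range = sgr_range,
    config = list(passes = as.integer(passes), forgetting = forgetting,
                  beta = beta, seed = as.integer(seed)),
    provenance = list(datasets = unique(data$dataset[!is.na(data$dataset)]),
                      n_train = nrow(data))
  ), class = "sgr_model")
}

#' @export
print.sgr_model <- function(x, ...) {
  cat(sprintf("<sgr_model> inputs {%s}, N=%d, lambda=%g, trained on %d records%s\n",
              paste(x$features, collapse = ", "),
              x$network$n_neurons, x$network$time_scale,
              x$provenance$n_train,
              if (length(x$provenance$datasets))
                paste0(" [", paste(x$provenance$datasets, collapse = "+"), "]")
              else ""))
  invisible(x)
}

#' Estimate SGR for new records
#'
#' Runs the reservoir from a zero state over the record sequence, applies
#' the trained linear readout, and converts the normalized outputs to
#' % day^-1 with the model's stored SGR range.
#'
#' Two input-normalization conventions are supported. With
#' `rescale_inputs = "training"` (the default, for records drawn from the
#' same population as the training data) features are normalized with the
#' *stored training* ranges; values outside the training envelope
#' extrapolate linearly, with a warning. With `rescale_inputs = "self"` —
#' the cross-population protocol — each feature is normalized by the
#' *application dataset's own* min-max, so a model can be applied to a
#' different stage or species whose absolute weight scale lies far outside
#' its training envelope: the model then reads the new population's
#' relative feature structure, and its inputs always stay in `[-1, 1]`.
#'
#' @param model An [train_model()] result (or one loaded by [read_model()]).
#' @param data A `fish_dataset` carrying the model's input features (`sgr`
#'   is not required). Extra columns are ignored: a two-input model fed
#'   three-column data uses only its declared inputs.
#' @param rescale_inputs `"training"` (stored ranges) or `"self"`
#'   (application data's own ranges; use for cross-stage / cross-species
#'   application).
#' @param warn_extrapolation Warn when inputs fall outside the training
#'   range (default TRUE; only relevant for `rescale_inputs = "training"`).
#' @return A data.frame with one row per record: `id`, `sgr_norm` (the raw
#'   network output) and `sgr_est` (% day^-1).
#' @export
estimate_sgr <- function(model, data, rescale_inputs = c("training", "self"),
                         warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "sgr_model"))
  rescale_inputs <- match.arg(rescale_inputs)
  data <- as_fish_dataset(data)
  check_features(data, model$features, need_sgr = FALSE)
  ranges <- if (rescale_inputs == "self") {
    if (nrow(data) < 2) {
      stop_validation("self-normalization needs at least 2 records")
    }
    setNames(lapply(model$features, function(f) range_of(data[[f]], f)),
             model$features)
  } else {
    model$feature_ranges
  }
  u <- vapply(model$features,
              function(f) normalize_feature(data[[f]], ranges[[f]]),
              numeric(nrow(data)))
  u <- matrix(u, ncol = length(model$features))
  if (rescale_inputs == "self") warn_extrapolation <- FALSE
  if (warn_extrapolation && any(abs(u) > 1 + 1e-12)) {
    n_out <- sum(apply(abs(u) > 1 + 1e-12, 1, any))
    warning(sprintf(
      "%d record(s) fall outside the training range of at least one feature; extrapolating linearly",
      n_out))
  }
  states <- run_reservoir(model$network, u)
  y <- drop(states %*% model$w_out)
  data.frame(id = data$id,
             sgr_norm = y,
             sgr_est = denormalize_feature(y, model$sgr_range),
             stringsAsFactors = FALSE)
}

#' Split a dataset into training and test parts
#'
#' Draws a seeded uniform random test subset of size
#' `max(1, round(n * test_fraction))` *per constituent dataset label* (so a
#' combined dataset contributes 15% of each part, matching the evaluation
#' convention), without replacement. Stored record order is preserved
#' within each side; the partition is exact (disjoint, exhaustive).
#'
#' @param data A `fish_dataset`.
#' @param test_fraction Fraction held out, in (0, 1); default 0.15.
#' @param seed Seed for the draw.
#' @return A list with elements `train`, `test` (both `fish_dataset`s) and
#'   `test_idx` (row indices of the test records in `data`).
#' @export
split_train_test <- function(data, test_fraction = 0.15, seed = 1) {
  data <- as_fish_dataset(data)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_validation("test_fraction must be in (0, 1)")
  }
  if (nrow(data) < 2) stop_validation("need at least 2 records to split")
  groups <- ifelse(is.na(data$dataset), "", data$dataset)
  test_idx <- integer(0)
  with_seed(seed, {
    for (g in unique(groups)) {
      rows <- which(groups == g)
      n_test <- max(1L, round(length(rows) * test_fraction))
      if (n_test >= length(rows)) {
        stop_validation(
          "dataset '%s' has %d record(s): too few to hold out a non-empty test side",
          g, length(rows))
      }
      test_idx <- c(test_idx, sample(rows, n_test))
    }
  })
  test_idx <- sort(test_idx)
  list(train = as_fish_dataset(as.data.frame(data)[-test_idx, , drop = FALSE]),
       test = as_fish_dataset(as.data.frame(data)[test_idx, , drop = FALSE]),
       test_idx = test_idx)
}

mse_report <- function(pred, target) {
  sq <- (pred - target)^2
  list(mse = mean(sq), sd = sd(sq), sq_errors = sq)
}

#' Evaluate a trained model on held-out records
#'
#' Estimates SGR for the test records and reports the mean and standard
#' deviation of the per-sample squared errors on the normalized scale (the
#' convention under which reported reservoir MSEs of order 1e-4 to 1e-1 are
#' to be read) and, for transparency, in real units (% day^-1)^2. Targets
#' are normalized with the model's stored SGR range.
#'
#' @param model An `sgr_model`.
#' @param test A non-empty `fish_dataset` whose records carry `sgr`.
#' @param warn_extrapolation Passed to [estimate_sgr()].
#' @return An object of class `sgr_evaluation`: `n`, `mse_norm`, `sd_norm`,
#'   `mse_real`, `sd_real`, and a `per_sample` data.frame with estimated and
#'   target SGR in both scales and the squared errors.
#' @export
evaluate_model <- function(model, test, warn_extrapolation = TRUE) {
  stopifnot(inherits(model, "sgr_model"))
  test <- as_fish_dataset(test)
  if (nrow(test) == 0) stop_validation("test set is empty")
  check_features(test, model$features, need_sgr = TRUE)
  est <- estimate_sgr(model, test, warn_extrapolation = warn_extrapolation)
  target_norm <- normalize_feature(test$sgr, model$sgr_range)
  rn <- mse_report(est$sgr_norm, target_norm)
  rr <- mse_report(est$sgr_est, test$sgr)
  structure(list(
    n = nrow(test),
    mse_norm = rn$mse, sd_norm = rn$sd,
    mse_real = rr$mse, sd_real = rr$sd,
    per_sample = data.frame(id = test$id,
                            sgr_norm_est = est$sgr_norm,
                            sgr_norm_target = target_norm,
                            sgr_est = est$sgr_est,
                            sgr_target = test$sgr,
                            sq_err_norm = rn$sq_errors,
                            sq_err_real = rr$sq_errors,
                            stringsAsFactors = FALSE)
  ), class = "sgr_evaluation")
}

#' @export
print.sgr_evaluation <- function(x, ...) {
  cat(sprintf("<sgr_evaluation> n=%d  MSE (normalized) %.4g +/- %.4g  MSE (%% day^-1)^2 %.4g +/- %.4g\n",
              x$n, x$mse_norm, x$sd_norm, x$mse_real, x$sd_real))
  invisible(x)
}

#' Input-ablation study over the seven feature sets
#'
#' Trains one model per input set on an identical train/test split (same
#' split seed, same reservoir seed for every set) and tabulates test MSEs,
#' ranked from best to worst. The question it answers: do weight, T/C ratio
#' and CF each carry independent SGR signal, i.e. does the three-input model
#' attain the minimal error?
#'
#' @param data A `fish_dataset` carrying all three features and `sgr`.
#' @param test_fraction Held-out fraction, default 0.15.
#' @param seed Seed controlling both the split and the reservoir.
#' @param ... Further arguments to [train_model()] (e.g. `time_scale`,
#'   `passes`).
#' @return A data.frame with one row per input set: `input_set`, `n_inputs`,
#'   `mse_norm`, `sd_norm`, `mse_real`, `sd_real`, `rank`, `best`; the
#'   attribute `three_input_best` flags whether the full set attains the
#'   minimal MSE, and attribute `reports` keeps the full `sgr_evaluation`s.
#' @export
ablation_study <- function(data, test_fraction = 0.15, seed = 1, ...) {
  data <- as_fish_dataset(data)
  check_features(data, c("weight_g", "tc_ratio", "cf"), need_sgr = TRUE)
  split <- split_train_test(data, test_fraction = test_fraction, seed = seed)
  sets <- input_sets()
  reports <- lapply(sets, function(fs) {
    m <- train_model(split$train, features = fs, seed = seed, ...)
    evaluate_model(m, split$test, warn_extrapolation = FALSE)
  })
  tab <- data.frame(
    input_set = names(sets),
    n_inputs = vapply(sets, length, integer(1)),
    mse_norm = vapply(reports, function(r) r$mse_norm, numeric(1)),
    sd_norm = vapply(reports, function(r) r$sd_norm, numeric(1)),
    mse_real = vapply(reports, function(r) r$mse_real, numeric(1)),
    sd_real = vapply(reports, function(r) r$sd_real, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab$rank <- rank(tab$mse_norm, ties.method = "first")
  tab$best <- tab$rank == 1L
  tab <- tab[order(tab$rank), ]
  rownames(tab) <- NULL
  attr(tab, "three_input_best") <- tab$input_set[tab$best] == "W+T/C+CF"
  attr(tab, "reports") <- reports
  tab
}
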