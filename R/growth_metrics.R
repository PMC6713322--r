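#' Specific growth rate, exponential form
#'
#' SGR (% day^-1) from body weights at two times, using the compound-growth
#' convention `SGR = 100 (e^g - 1)` with instantaneous growth coefficient
#' `g = (ln W2 - ln W1) / (t2 - t1)` (day^-1).
#'
#' @param w1,w2 Body weight in g at times `t1` and `t2`; must be positive.
#' @param t1,t2 Times in days; `t2` must exceed `t1`.
#' @return SGR in % day^-1 (negative when the fish lost weight).
#' @seealso [sgr_linear()] for the log-linear convention.
#' @examples
#' sgr_exponential(100, 110, 0, 10)
#' @export
sgr_exponential <- function(w1, w2, t1, t2) {
  g <- growth_coefficient(w1, w2, t1, t2)
  100 * (exp(g) - 1)
}

#' Specific growth rate, log-linear form
#'
#' SGR (% day^-1) as `100 (ln W2 - ln W1) / (t2 - t1)`, i.e. `100 g`. For
#' small `g` the two conventions agree to second order; the exponential form
#' is always the larger of the two when growth is positive.
#'
#' @inheritParams sgr_exponential
#' @return SGR in % day^-1.
#' @examples
#' sgr_linear(100, 110, 0, 10)
#' @export
sgr_linear <- function(w1, w2, t1, t2) {
  100 * growth_coefficient(w1, w2, t1, t2)
}

growth_coefficient <- function(w1, w2, t1, t2) {
  if (any(!is.finite(w1)) || any(!is.finite(w2)) || any(w1 <= 0) || any(w2 <= 0)) {
    stop_validation("weights must be positive and finite")
  }
  if (any(!is.finite(t1)) || any(!is.finite(t2)) || any(t2 <= t1)) {
    stop_validation("time interval must be positive (t2 > t1)")
  }
  (log(w2) - log(w1)) / (t2 - t1)
}

#' Fulton's condition factor
#'
#' `CF = 100 * weight / length^3` with weight in g and length in cm
#' (units 100 g cm^-3). At equal weight, a lower CF indicates relatively
#' greater skeletal (length) growth and is used here as an inverse proxy of
#' protein growth efficiency.
#'
#' @param weight Body weight in g, positive.
#' @param length Fork/total length in cm, positive.
#' @return Condition factor (dimensionless index, 100 g cm^-3).
#' @examples
#' condition_factor(1000, 46.4)
#' @export
condition_factor <- function(weight, length) {
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop_validation("weight must be positive and finite")
  }
  if (any(!is.finite(length)) || any(length <= 0)) {
    stop_validation("length must be positive and finite")
  }
  100 * weight / length^3
}

#' Feature range for min-max normalization
#'
#' A named `[min, max]` interval, computed from training data only and stored
#' with a trained model so that new records are mapped with the *training*
#' envelope (values outside it extrapolate linearly).
#'
#' @param name Feature identifier, e.g. `"weight_g"`, `"tc_ratio"`, `"cf"`,
#'   `"sgr"`.
#' @param min,max Range endpoints; `max >= min` required. A degenerate range
#'   (`max == min`) is accepted at construction but rejected by
#'   [normalize_feature()], since a constant feature carries no information.
#' @return An object of class `feature_range`.
#' @export
feature_range <- function(name, min, max) {
  if (!is.character(name) || length(name) != 1L) {
    stop_validation("feature_range name must be a single string")
  }
  if (!is.finite(min) || !is.finite(max) || max < min) {
    stop_validation("feature_range for '%s' requires finite max >= min", name)
  }
  structure(list(name = name, min = as.numeric(min), max = as.numeric(max)),
            class = "feature_range")
}

#' @export
print.feature_range <- function(x, ...) {
  cat(sprintf("<feature_range> %s: [%g, %g]\n", x$name, x$min, x$max))
  invisible(x)
}

range_of <- function(x, name) feature_range(name, min(x), max(x))

check_nondegenerate <- function(range) {
  if (range$max <= range$min) {
    stop_validation(
      "degenerate range for feature '%s' (min == max == %g): constant features carry no information",
      range$name, range$min)
  }
}

#' Min-max normalization to [-1, 1]
#'
#' Maps `range$min` to -1, `range$max` to +1 and the midpoint to 0 via
#' `2 (x - min) / (max - min) - 1`, matching the `[-1, 1]` working interval
#' of the reservoir's tanh activation. Values outside the range extrapolate
#' linearly beyond `[-1, 1]`; this is deliberate, since applying a trained
#' model across populations necessarily feeds values outside the training
#' envelope.
#'
#' @param x Numeric vector in original units.
#' @param range A [feature_range()] (non-degenerate).
#' @return Normalized values.
#' @seealso [denormalize_feature()], the exact inverse.
#' @export
normalize_feature <- function(x, range) {
  stopifnot(inherits(range, "feature_range"))
  check_nondegenerate(range)
  2 * (x - range$min) / (range$max - range$min) - 1
}

#' Inverse min-max normalization
#'
#' Exact inverse of [normalize_feature()]:
#' `min + (y + 1) (max - min) / 2`. Used to convert the network's normalized
#' SGR outputs back to % day^-1 using the stored SGR range of the training
#' data.
#'
#' @param y Numeric vector on the normalized scale.
#' @inheritParams normalize_feature
#' @return Values in original units.
#' @export
denormalize_feature <- function(y, range) {
  stopifnot(inherits(range, "feature_range"))
  check_nondegenerate(range)
  range$min + (y + 1) * (range$max - range$min) / 2
}
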