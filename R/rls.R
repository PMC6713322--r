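# Online recursive least squares for the linear readout. The auto-correlation
# matrix p starts at I/beta; with forgetting factor 1 a single pass over T
# samples reproduces the ridge-regularized batch solution
# (X'X + beta I)^{-1} X'd exactly — the oracle used in the tests.

#' Initialize the RLS readout state
#'
#' Readout weights start at zero; the auto-correlation matrix at
#' `p(0) = I / beta`.
#'
#' @param n_neurons Reservoir size N (length of the readout weight vector).
#' @param forgetting Forgetting factor `lambda_RLS` in (0, 1]. The default
#'   0.99 discounts old samples with a ~100-sample memory; 1 gives plain
#'   (regularized) least squares and is used for the batch-equivalence
#'   oracle.
#' @param beta Small constant setting the initial auto-correlation matrix;
#'   acts as a ridge penalty of strength `beta` at `forgetting = 1`.
#' @return An object of class `rls_state` with elements `w_out`, `p`,
#'   `forgetting`, `beta`, `step`.
#' @export
rls_state <- function(n_neurons, forgetting = 0.99, beta = 1e-4) {
  if (forgetting <= 0 || forgetting > 1) {
    stop_validation("forgetting factor must satisfy 0 < lambda_RLS <= 1")
  }
  if (beta <= 0) stop_validation("beta must be positive")
  structure(list(w_out = numeric(n_neurons),
                 p = diag(n_neurons) / beta,
                 forgetting = forgetting, beta = beta,
                 step = 0L),
            class = "rls_state")
}

#' Linear readout
#'
#' The single output neuron is linear: `y = W_out . x`.
#'
#' @param rls An [rls_state()].
#' @param x Reservoir state vector.
#' @return Scalar normalized output.
#' @export
readout <- function(rls, x) {
  stopifnot(inherits(rls, "rls_state"))
  if (length(x) != length(rls$w_out)) {
    stop_validation("state length %d does not match readout length %d",
                    length(x), length(rls$w_out))
  }
  sum(rls$w_out * x)
}

#' One recursive-least-squares update
#'
#' Given the current reservoir state `x` and target `d` (normalized SGR),
#' performs the standard RLS step with forgetting factor:
#' error `e = d - W_out . x`; gain `K = p x / (lambda_RLS + x' p x)`;
#' `p <- (p - K x' p) / lambda_RLS` (re-symmetrized to protect positive
#' definiteness against floating-point drift); `W_out <- W_out + K e`.
#' Updates occur at each input-target pair during online training.
#'
#' @inheritParams readout
#' @param d Scalar target on the normalized scale.
#' @return The updated `rls_state`; the instantaneous error is attached as
#'   element `last_error`.
#' @export
rls_update <- function(rls, x, d) {
  stopifnot(inherits(rls, "rls_state"))
  if (length(x) != length(rls$w_out)) {
    stop_validation("state length %d does not match readout length %d",
                    length(x), length(rls$w_out))
  }
  e <- d - sum(rls$w_out * x)
  px <- rls$p %*% x
  k <- drop(px) / (rls$forgetting + sum(x * px))
  p <- (rls$p - tcrossprod(k, drop(crossprod(x, rls$p)))) / rls$forgetting
  p <- (p + t(p)) / 2
  w <- rls$w_out + k * e
  if (!all(is.finite(p)) || !all(is.finite(w))) {
    stop_numerical("RLS update produced non-finite values at step %d",
                   rls$step + 1L)
  }
  rls$w_out <- w
  rls$p <- p
  rls$step <- rls$step + 1L
  rls$last_error <- e
  rls
}
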