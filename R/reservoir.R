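# The fixed random reservoir. Input and recurrent weights are drawn once
# from a seed and never trained; only the linear readout learns (see rls.R).

#' Construct a fixed random reservoir network
#'
#' Builds the echo-state reservoir: an `n_neurons` x `n_inputs` input weight
#' matrix with entries uniform on `[-input_scale, input_scale]`, and an
#' `n_neurons` x `n_neurons` recurrent matrix with entries uniform on
#' `[-1, 1]`. Both are sparsified to exactly `round(sparsity * n_entries)`
#' zero entries (randomly placed), and the recurrent matrix is then rescaled
#' so its spectral radius equals `spectral_radius` — below one, so the
#' reservoir state forgets its initial condition (echo-state property).
#' The construction is a pure function of `seed`; the matrices are fixed
#' thereafter.
#'
#' @param n_inputs Number of input neurons M (1-3 in typical use: weight,
#'   T/C ratio, CF, or a subset).
#' @param n_neurons Reservoir size N. Default 50: large enough for the
#'   three-factor SGR map, small enough to avoid overfitting small fish
#'   datasets.
#' @param time_scale Leak rate lambda in (0, 1]: the state update blends the
#'   previous state (weight `1 - lambda`) with the new tanh drive (weight
#'   `lambda`). Default 1 (no leak), appropriate for exchangeable per-fish
#'   records; smaller values add temporal smoothing for genuinely sequential
#'   data.
#' @param bias Constant hidden bias b0 keeping neurons weakly activated.
#' @param spectral_radius Target spectral radius of the recurrent matrix.
#' @param input_scale Half-width of the uniform input-weight distribution.
#' @param sparsity Fraction of exactly-zero entries in each weight matrix.
#' @param seed Integer RNG seed; identical seeds give entrywise-identical
#'   networks.
#' @return An object of class `reservoir_network`.
#' @examples
#' net <- reservoir_network(3, seed = 1)
#' @export
reservoir_network <- function(n_inputs, n_neurons = 50, time_scale = 1,
                              bias = 0.001, spectral_radius = 0.9,
                              input_scale = 0.1, sparsity = 0.5, seed = 1) {
  if (n_neurons < 1 || n_inputs < 1) {
    stop_validation("n_neurons and n_inputs must be >= 1")
  }
  if (time_scale <= 0 || time_scale > 1) {
    stop_validation("time_scale (lambda) must satisfy 0 < lambda <= 1")
  }
  if (sparsity < 0 || sparsity >= 1) {
    stop_validation("sparsity must be in [0, 1)")
  }
  with_seed(seed, {
    w_in <- matrix(runif(n_neurons * n_inputs, -input_scale, input_scale),
                   n_neurons, n_inputs)
    w_in[sample(length(w_in))[seq_len(round(sparsity * length(w_in)))]] <- 0
    w_sys <- matrix(runif(n_neurons * n_neurons, -1, 1), n_neurons, n_neurons)
    w_sys[sample(length(w_sys))[seq_len(round(sparsity * length(w_sys)))]] <- 0
    rho <- spectral_radius_of(w_sys)
    if (rho < 1e-12) {
      stop_validation(
        "sparsified recurrent matrix is (numerically) nilpotent (spectral radius %g); use a different seed",
        rho)
    }
    w_sys <- w_sys * (spectral_radius / rho)
    structure(list(n_neurons = as.integer(n_neurons),
                   n_inputs = as.integer(n_inputs),
                   time_scale = time_scale, bias = bias,
                   spectral_radius = spectral_radius,
                   input_scale = input_scale, sparsity = sparsity,
                   seed = as.integer(seed),
                   w_in = w_in, w_sys = w_sys),
              class = "reservoir_network")
  })
}

spectral_radius_of <- function(w) {
  max(Mod(eigen(w, only.values = TRUE)$values))
}

#' @export
print.reservoir_network <- function(x, ...) {
  cat(sprintf(
    "<reservoir_network> N=%d neurons, M=%d inputs, lambda=%g, rho=%g, seed=%d\n",
    x$n_neurons, x$n_inputs, x$time_scale, x$spectral_radius, x$seed))
  invisible(x)
}

#' One reservoir state update
#'
#' Leaky-integrator discrete dynamics
#' `x' = (1 - lambda) x + lambda tanh(W_in u + W_sys x + b0)`, componentwise.
#' Starting from `x = 0`, every component stays in `[-1, 1]` for any input
#' sequence (each update is a convex combination of the previous state and a
#' tanh output).
#'
#' @param net A [reservoir_network()].
#' @param x Current state, length `n_neurons` (use `numeric(n_neurons)` i.e.
#'   zeros to start).
#' @param u Input vector, length `n_inputs`, on the normalized `[-1, 1]`
#'   scale (linear extrapolation beyond it is tolerated).
#' @return The next state vector.
#' @export
reservoir_step <- function(net, x, u) {
  stopifnot(inherits(net, "reservoir_network"))
  if (length(u) != net$n_inputs) {
    stop_validation("input has length %d but the network expects %d",
                    length(u), net$n_inputs)
  }
  if (length(x) != net$n_neurons) {
    stop_validation("state has length %d but the network has %d neurons",
                    length(x), net$n_neurons)
  }
  lam <- net$time_scale
  (1 - lam) * x +
    lam * tanh(drop(net$w_in %*% u) + drop(net$w_sys %*% x) + net$bias)
}

#' Run the reservoir over a sequence of inputs
#'
#' Iterates [reservoir_step()] over the rows of `u_seq` and collects the
#' state visited after absorbing each input — the state the readout sees for
#' that record.
#'
#' @inheritParams reservoir_step
#' @param u_seq Numeric matrix, one row per record, `n_inputs` columns.
#' @param x0 Initial state; defaults to zeros (no washout is applied; the
#'   sub-unit spectral radius makes the influence of the start state decay
#'   geometrically).
#' @return A `nrow(u_seq)` x `n_neurons` matrix of states.
#' @export
run_reservoir <- function(net, u_seq, x0 = NULL) {
  stopifnot(inherits(net, "reservoir_network"))
  u_seq <- as.matrix(u_seq)
  if (ncol(u_seq) != net$n_inputs) {
    stop_validation("input sequence has %d columns but the network expects %d",
                    ncol(u_seq), net$n_inputs)
  }
  x <- if (is.null(x0)) numeric(net$n_neurons) else x0
  states <- matrix(0, nrow(u_seq), net$n_neurons)
  for (t in seq_len(nrow(u_seq))) {
    x <- reservoir_step(net, x, u_seq[t, ])
    states[t, ] <- x
  }
  states
}
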