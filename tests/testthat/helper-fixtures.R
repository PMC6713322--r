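# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code under fixed seeds; nothing is read from disk.

# Ridge-regularized batch least squares: the closed-form solution that one
# online RLS pass with forgetting factor 1 must reproduce.
batch_lsq <- function(X, d, beta = 1e-4) {
  solve(crossprod(X) + beta * diag(ncol(X)), crossprod(X, d))
}

# Spectral-radius estimate from the asymptotic growth rate of ||A^k v||,
# independent of eigen(); loose tolerance (complex-pair oscillation limits
# precision), used as a cross-check only.
growth_rate_radius <- function(a, burn = 200, steps = 200) {
  v <- rep(1, ncol(a)) / sqrt(ncol(a))
  for (k in seq_len(burn)) {
    v <- drop(a %*% v)
    v <- v / sqrt(sum(v^2))
  }
  lognorm <- 0
  for (k in seq_len(steps)) {
    v <- drop(a %*% v)
    nv <- sqrt(sum(v^2))
    lognorm <- lognorm + log(nv)
    v <- v / nv
  }
  exp(lognorm / steps)
}

# A dataset whose sgr is an exact affine function of the min-max-normalized
# features (the map the linear readout should realize almost perfectly).
make_linear_dataset <- function(n, seed) {
  d <- generate_dataset(stage_preset("adult"), n = n, seed = seed)
  nm <- function(x) 2 * (x - min(x)) / (max(x) - min(x)) - 1
  d$sgr <- 1.5 + 0.3 * nm(d$weight_g) - 0.5 * nm(d$tc_ratio) + 0.2 * nm(d$cf)
  d$sgr_true <- d$sgr
  d
}

# Minimal valid dataset of a given size (for split arithmetic etc.).
make_min_dataset <- function(n, label = NA) {
  as_fish_dataset(data.frame(
    weight_g = seq(100, 200, length.out = n),
    length_cm = 20,
    tc_ratio = seq(2, 6, length.out = n),
    sgr = seq(0.5, 2.5, length.out = n)
  ), dataset = label)
}

# A bare reservoir_network with hand-chosen weights, for closed-form state
# update checks (bypasses the random constructor on purpose).
manual_network <- function(w_in, w_sys, time_scale = 1, bias = 0.001) {
  structure(list(n_neurons = nrow(w_sys), n_inputs = ncol(w_in),
                 time_scale = time_scale, bias = bias,
                 spectral_radius = NA_real_, input_scale = NA_real_,
                 sparsity = NA_real_, seed = NA_integer_,
                 w_in = w_in, w_sys = w_sys),
            class = "reservoir_network")
}

# Cache for the ablation runs shared by the ordering and noise-floor checks.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_ablation_runs <- function(seeds = 1:10, n = 400) {
  key <- paste0("abl_", paste(range(seeds), collapse = "_"), "_", n)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  runs <- lapply(seeds, function(s) {
    d <- generate_dataset(stage_preset("adult"), n = n, seed = s)
    tab <- ablation_study(d, seed = s)
    m <- train_model(split_train_test(d, seed = s)$train)
    sigma_norm <- ground_truth_params()$noise_sd *
      2 / (m$sgr_range$max - m$sgr_range$min)
    list(tab = tab, sigma_norm = sigma_norm)
  })
  .acceptance_cache[[key]] <- runs
  runs
}
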