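# sgrnet

Estimation of fish **weight specific growth rate** (SGR, % day⁻¹) from
single-sampling biology, for fisheries and aquaculture scientists who cannot
weigh the same individual twice — wild populations above all. The estimator
is an **echo state network**: a fixed sparse random recurrent reservoir
whose linear readout is trained online by **recursive least squares** on
three factors measurable at one sampling:

* **weight** (g) — age/growth-stage proxy; younger fish grow faster;
* **T/C ratio** — trypsin/chymotrypsin activity ratio in the pyloric caeca,
  a digestive-efficiency index of growth potential;
* **condition factor** CF = 100·W/L³ (g, cm) — inverse proxy of protein
  growth efficiency.

The core model, for normalized inputs **u**(t) and state **x**(t):

```
x(t+1) = (1 − λ) x(t) + λ tanh(W_in u(t+1) + W_sys x(t) + b0)
y(t)   = W_out x(t)
```

with N = 50 neurons, spectral radius ρ(W_sys) = 0.9, 50% sparsity, input
weights on [−0.1, 0.1], bias b0 = 0.001. Only W_out learns, per record:

```
e = d − y;  K = p x / (λ_RLS + xᵀ p x);  p ← (p − K xᵀ p)/λ_RLS;  W_out ← W_out + K e
```

(λ_RLS = 0.99, p(0) = I/10⁻⁴). Inputs and SGR are min–max normalized to
[−1, 1]; estimates are returned in % day⁻¹ via the training data's stored
SGR range. Because the real multi-stage datasets behind the method exist
only as published figures, the package includes a seeded synthetic
generator with juvenile-to-adult stage presets and a documented ground
truth, so every property is reproducible from code alone.

## Worked example

```r
library(sgrnet)

d  <- generate_dataset(stage_preset("adult"), n = 400, seed = 1)  # synthetic trial
sp <- split_train_test(d, seed = 1)                               # 85/15, seeded
m  <- train_model(sp$train, seed = 1)
m
#> <sgr_model> inputs {weight_g, tc_ratio, cf}, N=50, lambda=1, trained on 340 records [adult]

evaluate_model(m, sp$test, warn_extrapolation = FALSE)
#> <sgr_evaluation> n=60  MSE (normalized) 0.007494 +/- 0.01034  MSE (% day^-1)^2 0.005075 +/- 0.007004
```

The held-out mean squared error is reported on the normalized scale (the
convention for reservoir readout errors) and in real units: here the model
estimates SGR of unseen fish to about ±0.07 % day⁻¹ RMS against targets
spanning ~0.5–2 % day⁻¹. Which inputs carry the signal:

```r
tab <- ablation_study(d, seed = 1)
tab[, c("input_set", "n_inputs", "mse_norm", "rank")]
#>   input_set n_inputs mse_norm rank
#> 1  W+T/C+CF        3  0.00749    1
#> 2    T/C+CF        2  0.01852    2
#> 3     W+T/C        2  0.02083    3
#> 4       T/C        1  0.03253    4
#> 5        CF        1  0.08645    5
#> 6      W+CF        2  0.08775    6
#> 7         W        1  0.08993    7
attr(tab, "three_input_best")
#> [1] TRUE
```

The full three-factor combination attains the lowest error, and every set
containing the T/C ratio beats every set without it — the digestive-
efficiency signal dominates. To apply a trained model across stages or
species (where absolute weights lie far outside the training envelope), use
the cross-population protocol, which normalizes the application dataset by
its own ranges:

```r
pops <- generate_ranked_populations(seed = 1)      # A > C > B by construction
est  <- estimate_sgr(m, combine_datasets(pops), rescale_inputs = "self")
```

Models trained on different stages agree on the population *ranking* even
when their absolute estimates differ. Closed-form helpers are included:
`sgr_exponential(100, 110, 0, 10)` → `0.9576583`,
`condition_factor(1000, 46.4)` → `1.001028`.

A command-line interface (installed as `exec/sgrnet`) wraps the same
functions: `simulate`, `train`, `estimate`, `evaluate`, `ablate`; every run
writes a manifest with its configuration and seeds, and model files
round-trip bit-exactly.

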