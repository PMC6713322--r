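test_that("test-set sizes follow the nearest-integer rule with minimum 1", {
  sizes <- c(20, 24, 79, 109, 499)
  expected <- c(3, 4, 12, 16, 75)
  for (i in seq_along(sizes)) {
    sp <- split_train_test(make_min_dataset(sizes[i]), 0.15, seed = 1)
    expect_equal(nrow(sp$test), expected[i])
    expect_equal(nrow(sp$train), sizes[i] - expected[i])
  }
  # tiny n still holds out at least one
  sp <- split_train_test(make_min_dataset(4), 0.15, seed = 1)
  expect_equal(nrow(sp$test), 1)
})

test_that("the split is an exact, seeded, per-dataset partition", {
  d <- combine_datasets(list(a = make_min_dataset(40), b = make_min_dataset(40)))
  sp1 <- split_train_test(d, 0.15, seed = 9)
  sp2 <- split_train_test(d, 0.15, seed = 9)
  expect_identical(sp1$test_idx, sp2$test_idx)
  # 15% of each constituent part, not of the pool
  expect_equal(sum(sp1$test$dataset == "a"), 6)
  expect_equal(sum(sp1$test$dataset == "b"), 6)
  # disjoint and exhaustive
  expect_equal(sort(c(sp1$train$id, sp1$test$id)), sort(d$id))
  expect_length(intersect(sp1$train$id, sp1$test$id), 0)
  expect_error(split_train_test(d, 0), class = "sgrnet_validation_error")
  expect_error(split_train_test(d, 1), class = "sgrnet_validation_error")
})

test_that("training is deterministic and validates its inputs", {
  d <- generate_dataset(stage_preset("post_smolt"), n = 30, seed = 2)
  m1 <- train_model(d, seed = 5)
  m2 <- train_model(d, seed = 5)
  expect_identical(m1, m2)
  e1 <- estimate_sgr(m1, d); e2 <- estimate_sgr(m2, d)
  expect_identical(e1$sgr_est, e2$sgr_est)
  # single record cannot be trained on
  expect_error(train_model(as.data.frame(d)[1, , drop = FALSE]),
               class = "sgrnet_validation_error")
  # missing sgr is reported with the record ids
  d_miss <- as.data.frame(d); d_miss$sgr[c(3, 7)] <- NA
  expect_error(train_model(as_fish_dataset(d_miss)),
               paste(d$id[3]), class = "sgrnet_validation_error")
  expect_error(train_model(d, features = "fin_count"),
               class = "sgrnet_validation_error")
})

test_that("the readout realizes an affine map of normalized inputs almost exactly", {
  mses <- vapply(1:5, function(s) {
    d <- make_linear_dataset(400, s)
    sp <- split_train_test(d, seed = s)
    m <- train_model(sp$train, seed = s)
    evaluate_model(m, sp$test, warn_extrapolation = FALSE)$mse_norm
  }, numeric(1))
  expect_lt(median(mses), 1e-4)
  expect_lt(max(mses), 1e-3)
  # and reproduces its own training targets to the same accuracy
  d <- make_linear_dataset(400, 1)
  m <- train_model(d, seed = 1)
  expect_lt(evaluate_model(m, d, warn_extrapolation = FALSE)$mse_norm, 1e-4)
})

test_that("estimates denormalize with the stored SGR range and ignore extra columns", {
  d <- generate_dataset(stage_preset("adult"), n = 50, seed = 3)
  m <- train_model(d, features = c("weight_g", "tc_ratio"), seed = 3)
  # a two-input model fed three-column data uses only its declared inputs
  est_full <- estimate_sgr(m, d)
  d_two <- as.data.frame(d); d_two$cf <- NA; d_two$length_cm <- 30
  est_two <- estimate_sgr(m, as_fish_dataset(d_two))
  expect_identical(est_full$sgr_norm, est_two$sgr_norm)
  # denormalization is the affine image of the normalized outputs
  expect_equal(est_full$sgr_est,
               m$sgr_range$min + (est_full$sgr_norm + 1) *
                 (m$sgr_range$max - m$sgr_range$min) / 2,
               tolerance = 1e-12)
  # midpoint convention
  expect_equal(denormalize_feature(0, feature_range("sgr", 0.4, 2.8)), 1.6)
  # missing feature -> validation error
  d_none <- as.data.frame(d); d_none$tc_ratio <- 2; d_none$tc_ratio[4] <- NA
  expect_error(estimate_sgr(m, d_none), class = "sgrnet_validation_error")
})

test_that("a shared record suffix forgets its prefix (echo-state estimation)", {
  m <- train_model(generate_dataset(stage_preset("adult"), n = 300, seed = 7),
                   seed = 7)
  pre1 <- generate_dataset(stage_preset("adult"), n = 250, seed = 11)
  pre2 <- generate_dataset(stage_preset("adult"), n = 250, seed = 12)
  suf <- generate_dataset(stage_preset("adult"), n = 260, seed = 13)
  e1 <- estimate_sgr(m, combine_datasets(list(p = pre1, s = suf)),
                     warn_extrapolation = FALSE)
  e2 <- estimate_sgr(m, combine_datasets(list(p = pre2, s = suf)),
                     warn_extrapolation = FALSE)
  # after >= 200 shared inputs the prefix's influence is below 1e-3
  last <- nrow(e1)
  expect_lt(abs(e1$sgr_norm[last] - e2$sgr_norm[last]), 1e-3)
})

test_that("evaluation reports mean and SD of per-sample squared errors", {
  r <- sgrnet:::mse_report(c(0, 1), c(0, 0))
  expect_equal(r$sq_errors, c(0, 1))
  expect_equal(r$mse, 0.5)
  expect_equal(r$sd, 0.70711, tolerance = 1e-5)
  # permutation invariance of the mean
  set.seed(1); p <- runif(20); t0 <- runif(20); perm <- sample(20)
  expect_equal(sgrnet:::mse_report(p, t0)$mse,
               sgrnet:::mse_report(p[perm], t0[perm])$mse)
  # perfect predictions
  expect_equal(sgrnet:::mse_report(p, p)$mse, 0)
  # evaluate_model wires the report together consistently
  d <- generate_dataset(stage_preset("adult"), n = 60, seed = 4)
  sp <- split_train_test(d, seed = 4)
  m <- train_model(sp$train, seed = 4)
  ev <- evaluate_model(m, sp$test, warn_extrapolation = FALSE)
  expect_equal(ev$mse_norm, mean(ev$per_sample$sq_err_norm))
  expect_equal(ev$n, nrow(sp$test))
  expect_error(evaluate_model(m, sp$test[0, ]), class = "sgrnet_validation_error")
})

test_that("the ablation table covers the seven sets deterministically", {
  d <- generate_dataset(stage_preset("adult"), n = 120, seed = 6)
  t1 <- ablation_study(d, seed = 6)
  t2 <- ablation_study(d, seed = 6)
  expect_equal(nrow(t1), 7)
  expect_setequal(t1$input_set, names(input_sets()))
  expect_identical(t1$mse_norm, t2$mse_norm)
  expect_equal(sum(t1$best), 1)
  expect_equal(t1$rank, 1:7)                       # returned ranked
  expect_type(attr(t1, "three_input_best"), "logical")
  # every set was evaluated on the same split
  ns <- vapply(attr(t1, "reports"), function(r) r$n, numeric(1))
  expect_true(all(ns == ns[1]))
})
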