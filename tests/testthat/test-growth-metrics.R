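test_that("SGR formulas match direct closed-form evaluation", {
  g <- (log(110) - log(100)) / 10
  expect_equal(sgr_exponential(100, 110, 0, 10), 100 * (exp(g) - 1),
               tolerance = 1e-12)
  expect_equal(sgr_linear(100, 110, 0, 10), 100 * g, tolerance = 1e-12)
  # conventional five-decimal values
  expect_equal(sgr_exponential(100, 110, 0, 10), 0.95766, tolerance = 1e-5)
  expect_equal(sgr_linear(100, 110, 0, 10), 0.95310, tolerance = 1e-5)
  # negative growth is allowed and mirrors through g's sign
  expect_equal(sgr_exponential(110, 100, 5, 15), 100 * (exp(-g) - 1),
               tolerance = 1e-12)
  expect_equal(sgr_exponential(110, 100, 5, 15), -0.94855, tolerance = 1e-4)
  # no growth
  expect_equal(sgr_exponential(100, 100, 0, 37), 0)
  expect_equal(sgr_linear(100, 100, 0, 37), 0)
  # the interval, not the absolute times, matters
  expect_equal(sgr_exponential(50, 60, 100, 110), sgr_exponential(50, 60, 0, 10))
})

test_that("SGR formulas reject non-positive weights and intervals", {
  expect_error(sgr_exponential(0, 100, 0, 10), class = "sgrnet_validation_error")
  expect_error(sgr_exponential(100, -5, 0, 10), class = "sgrnet_validation_error")
  expect_error(sgr_linear(100, 110, 10, 10), class = "sgrnet_validation_error")
  expect_error(sgr_linear(100, 110, 10, 5), class = "sgrnet_validation_error")
})

test_that("exponential and linear SGR obey their order and Taylor relations", {
  # e^g - 1 >= g, with equality only at g = 0
  for (w2 in c(101, 110, 150, 300)) {
    expect_gte(sgr_exponential(100, w2, 0, 10), sgr_linear(100, w2, 0, 10))
  }
  # linear form is antisymmetric under swapping W1 <-> W2
  expect_equal(sgr_linear(100, 137, 0, 10), -sgr_linear(137, 100, 0, 10),
               tolerance = 1e-12)
  # |SGR_exp - SGR_lin| <= 100 g^2 for |g| <= 0.05 (second-order Taylor bound)
  for (g in seq(-0.05, 0.05, by = 0.005)) {
    if (g == 0) next
    w2 <- 100 * exp(g * 10)
    diff <- abs(sgr_exponential(100, w2, 0, 10) - sgr_linear(100, w2, 0, 10))
    expect_lte(diff, 100 * g^2)
  }
})

test_that("condition factor follows 100 w / l^3 and its scaling law", {
  expect_equal(condition_factor(10, 10), 1)
  expect_equal(condition_factor(8, 2), 100)
  expect_equal(condition_factor(1000, 46.4), 100 * 1000 / 46.4^3,
               tolerance = 1e-12)
  # doubling length at fixed weight divides CF by 8 exactly
  expect_equal(condition_factor(500, 40), 8 * condition_factor(500, 80),
               tolerance = 1e-12)
  expect_error(condition_factor(-1, 10), class = "sgrnet_validation_error")
  expect_error(condition_factor(10, 0), class = "sgrnet_validation_error")
})

test_that("min-max normalization maps the range onto [-1, 1] and extrapolates", {
  r <- feature_range("x", 2, 6)
  expect_equal(normalize_feature(2, r), -1)
  expect_equal(normalize_feature(6, r), 1)
  expect_equal(normalize_feature(4, r), 0)
  expect_equal(normalize_feature(8, r), 2)   # linear beyond the range
  expect_equal(normalize_feature(0, r), -2)
  sgr <- feature_range("sgr", 0.4, 2.8)
  expect_equal(denormalize_feature(0, sgr), 1.6)
  expect_equal(denormalize_feature(1, sgr), 2.8)
  expect_equal(denormalize_feature(-1, sgr), 0.4)
})

test_that("normalize and denormalize are exact mutual inverses", {
  set.seed(42)
  for (i in 1:5) {
    r <- feature_range("x", runif(1, -10, 0), runif(1, 1, 100))
    x <- runif(100, r$min - 5, r$max + 5)
    expect_lt(max(abs(denormalize_feature(normalize_feature(x, r), r) - x)),
              1e-12)
    y <- runif(100, -2, 2)
    expect_lt(max(abs(normalize_feature(denormalize_feature(y, r), r) - y)),
              1e-12)
  }
})

test_that("degenerate feature ranges are rejected", {
  r <- feature_range("const", 3, 3)
  expect_error(normalize_feature(3, r), class = "sgrnet_validation_error")
  expect_error(denormalize_feature(0, r), class = "sgrnet_validation_error")
  expect_error(feature_range("bad", 5, 2), class = "sgrnet_validation_error")
})
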