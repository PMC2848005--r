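test_that("noiseless data are interpolated exactly by the full model", {
  m <- generating_model("HA")
  set.seed(5)
  X <- MASS::mvrnorm(100, rep(0, 12), m$correlation)
  d <- tibble::as_tibble(as.data.frame(X))
  names(d) <- paste0("x", 1:12)
  d$y <- drop(X %*% m$coefficients)
  fit <- fit_ols(d, intercept = FALSE)
  td <- suppressWarnings(tidy(fit)) # lm warns about the perfect fit
  expect_equal(td$estimate, m$coefficients, tolerance = 1e-10)
  expect_lt(suppressWarnings(glance(fit))$sigma, 1e-8)
})

test_that("estimates, SEs and CIs match a normal-equations oracle", {
  set.seed(31)
  for (rep in 1:4) {
    n <- 20; p <- 3
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    d <- tibble::as_tibble(as.data.frame(X))
    d$y <- y
    for (ic in c(TRUE, FALSE)) {
      td <- tidy(fit_ols(d, intercept = ic))
      o <- ols_oracle(X, y, intercept = ic)
      expect_equal(td$estimate, unname(o$estimate), tolerance = 1e-10)
      expect_equal(td$std.error, unname(o$se), tolerance = 1e-10)
      expect_equal(td$conf.low, unname(o$lower), tolerance = 1e-10)
      expect_equal(td$conf.high, unname(o$upper), tolerance = 1e-10)
    }
  }
})

test_that("a bivariate fit on the proxy predictor sees the inflated slope", {
  d <- simulate_dataset(generating_model("HA"), 2000, seed = 77)
  td <- tidy(fit_ols(d, predictors = "x4"))
  est <- td[td$term == "x4", ]
  expect_lt(abs(est$estimate - 10.80), 3 * est$std.error)
})

test_that("degenerate designs are signalled", {
  d <- tibble::tibble(x1 = 1:10, x2 = 2 * (1:10), y = rnorm(10))
  expect_error(fit_ols(d), "singular")
  expect_error(fit_ols(d[1:2, ], predictors = c("x1", "x2")), "observations")
  expect_error(fit_ols(d, predictors = character(0)), "at least one")
})

test_that("full-model coverage is calibrated and bias is centred at zero", {
  m <- generating_model("HA")
  bc <- bias_coverage(m, n = 400, replicates = 120, mode = "full", seed = 14)
  expect_true(all(abs(bc$bias) < 0.15))
  # binomial error around nominal 95 at 120 replicates
  expect_true(all(bc$coverage_pct > 95 - 3.5 * sqrt(95 * 5 / 120)))

  h0 <- bias_coverage(generating_model("H0"), n = 400, replicates = 80,
                      mode = "bivariate", seed = 15)
  expect_true(all(abs(h0$bias) < 0.02))
  expect_true(all(h0$coverage_pct > 85))
})

test_that("bivariate bias equals the spurious-slope excess", {
  m <- generating_model("HA")
  bc <- bias_coverage(m, n = 500, replicates = 100, mode = "bivariate",
                      seed = 16)
  expected_bias <- true_bivariate_beta(m) - m$coefficients
  # Monte-Carlo SE of a bivariate slope at n = 500 is well under 0.1
  expect_equal(bc$bias, expected_bias, tolerance = 0.12)
  # correlated proxies never cover the generating coefficient
  expect_equal(bc$coverage_pct[1:4], rep(0, 4))
})

test_that("intercept and intercept-free summaries agree closely", {
  m <- generating_model("HA")
  with_i <- bias_coverage_table(m, n = 400, replicates = 60, intercept = TRUE,
                                seed = 17)
  no_i <- bias_coverage_table(m, n = 400, replicates = 60, intercept = FALSE,
                              seed = 17)
  expect_lt(max(abs(with_i$full_bias - no_i$full_bias)), 0.05)
  expect_equal(with_i$single_coverage[1:4], no_i$single_coverage[1:4])
  expect_equal(names(with_i)[1:7],
               c("predictor", "true_value", "correlated", "full_bias",
                 "full_coverage", "single_bias", "single_coverage"))
})
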