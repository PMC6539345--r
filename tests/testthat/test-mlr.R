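test_that("exact linear data give a perfect fit", {
  d <- tibble::tibble(x1 = as.numeric(1:6), y = 2 * (1:6) + 5)
  m <- suppressWarnings(fit_qsrr(d, "y", "x1"))
  co <- suppressWarnings(tidy(m))
  expect_equal(co$estimate[co$term == "(Intercept)"], 5, tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "x1"], 2, tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
  expect_equal(m$sdec, 0, tolerance = 1e-7)
  expect_equal(suppressWarnings(q2_loo(d, "y", "x1")), 1, tolerance = 1e-10)
})

test_that("coefficients agree with the normal-equations oracle", {
  set.seed(7)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("x1", "x2")))
  y <- 1 + 2 * X[, 1] - 3 * X[, 2] + rnorm(6, 0, 0.1)
  d <- dplyr::bind_cols(tibble::as_tibble(X), tibble::tibble(y = y))
  m <- fit_qsrr(d, "y", c("x1", "x2"))
  expect_equal(tidy(m)$estimate, normal_equations_oracle(X, y),
               tolerance = 1e-10)
})

test_that("intercept models have residuals summing to zero and errors on rank deficiency", {
  d <- toy_modelling_data()
  m <- fit_qsrr(d, "y", c("x1", "x2", "x3"))
  expect_lt(abs(sum(m$residuals)), 1e-8 * stats::sd(d$y))
  d$x_dup <- d$x1
  expect_error(fit_qsrr(d, "y", c("x1", "x_dup")), "collinear")
})

test_that("sdec follows the root-mean-square convention", {
  expect_equal(sdec(c(0, 0, 0)), 0)
  expect_equal(sdec(c(3, -4)), sqrt(25 / 2))
  expect_equal(sdec(c(3, -4), "n_minus_p_1", p = 0), 5)
})

test_that("standardised coefficients are scale-free and reduce to the correlation", {
  d <- toy_modelling_data()
  m <- fit_qsrr(d, "y", c("x1", "x2"))
  b1 <- standardize_coefficients(m)
  d2 <- d; d2$x1 <- d2$x1 * 1000
  m2 <- fit_qsrr(d2, "y", c("x1", "x2"))
  expect_equal(standardize_coefficients(m2), b1, tolerance = 1e-10)
  # single-predictor standardised slope equals the sample correlation
  m3 <- fit_qsrr(d, "y", "x1")
  expect_equal(unname(standardize_coefficients(m3)),
               stats::cor(d$x1, d$y), tolerance = 1e-10)
})

test_that("leverage-shortcut Q2_loo equals explicit refitting", {
  d <- toy_modelling_data(n = 20, p = 4, seed = 5)
  desc <- paste0("x", 1:4)
  expect_equal(q2_loo(d, "y", desc), q2_loo_refit_oracle(d, "y", desc),
               tolerance = 1e-9)
  # a 6-point toy checked the same way
  d6 <- toy_modelling_data(n = 6, p = 1, seed = 9)
  expect_equal(q2_loo(d6, "y", "x1"), q2_loo_refit_oracle(d6, "y", "x1"),
               tolerance = 1e-10)
})

test_that("PRESS is never below the residual sum of squares", {
  for (seed in 1:5) {
    d <- toy_modelling_data(n = 15 + seed, p = 3, seed = seed, noise = 2)
    desc <- paste0("x", 1:3)
    fit <- fit_qsrr(d, "y", desc)
    rss <- sum(fit$residuals^2)
    expect_gte(press(d, "y", desc), rss)
    expect_lte(fit$q2_loo, fit$r_squared)
  }
})

test_that("predictions are invariant under affine descriptor rescaling", {
  d <- toy_modelling_data()
  m <- fit_qsrr(d, "y", c("x1", "x2"))
  d2 <- d; d2$x1 <- 100 * d$x1 - 7
  m2 <- fit_qsrr(d2, "y", c("x1", "x2"))
  expect_equal(predict(m2, d2), predict(m, d), tolerance = 1e-9)
})
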