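test_that("the cumulative model and its inverse behave as closed forms say", {
  expect_equal(weibull_cdf(10, alpha = 3.7, a0 = 10), 1 - exp(-1))
  expect_equal(weibull_cdf(4, alpha = 1, a0 = 8), 1 - exp(-0.5)) # exponential
  expect_equal(weibull_cdf(0, alpha = 2, a0 = 5), 0)
  expect_error(weibull_cdf(1, alpha = -1, a0 = 5))

  expect_equal(weibull_quantile(1 - exp(-1), alpha = 2.2, a0 = 14), 14)
  expect_equal(weibull_quantile(0.5, alpha = 1, a0 = 6), 6 * log(2))
  expect_error(weibull_quantile(1, alpha = 1, a0 = 1))

  pgrid <- seq(0.01, 0.99, by = 0.014)
  for (alpha in c(0.7, 1, 2.5)) {
    back <- weibull_cdf(weibull_quantile(pgrid, alpha, 12), alpha, 12)
    expect_equal(back, pgrid, tolerance = 1e-12)
  }
  # strictly increasing in a
  a <- seq(0.1, 40, by = 0.1)
  expect_true(all(diff(weibull_cdf(a, 1.5, 10)) > 0))
})

test_that("linearization maps exact Weibull data onto the stated line", {
  expect_equal(linearize(10, 1 - exp(-1))$y, 0)
  expect_equal(linearize(1, 0.5)$y, log(log(2)), tolerance = 1e-12)
  expect_error(linearize(1, 1))
  expect_error(linearize(-1, 0.5))

  a <- seq(2, 40, length.out = 25)
  pts <- linearize(a, weibull_cdf(a, alpha = 2, a0 = 10))
  fit <- stats::lm(y ~ x, data = pts)
  expect_equal(unname(coef(fit)[2]), 2, tolerance = 1e-10)
  expect_lt(max(abs(residuals(fit))), 1e-10)
})

test_that("plotting positions follow the chosen scheme", {
  expect_equal(plotting_positions(1), 0.5) # 0.7 / 1.4
  expect_equal(plotting_positions(3, "mean_rank"), c(0.25, 0.5, 0.75))
  p <- plotting_positions(1000)
  expect_true(all(diff(p) > 0) && all(p > 0) && all(p < 1))
  expect_error(plotting_positions(0))
})

test_that("rank regression recovers parameters exactly on quantile data", {
  p <- plotting_positions(50)
  fit <- fit_weibull(weibull_quantile(p, alpha = 2, a0 = 10))
  expect_equal(fit$alpha, 2, tolerance = 1e-6)
  expect_equal(fit$a0, 10, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  for (alpha in c(0.5, 1.3, 5)) {
    for (a0 in c(1, 27, 100)) {
      f <- fit_weibull(weibull_quantile(plotting_positions(40), alpha, a0))
      expect_equal(f$alpha, alpha, tolerance = 1e-8)
      expect_equal(f$a0, a0, tolerance = 1e-8)
    }
  }
})

test_that("rank regression recovers parameters from Monte-Carlo samples", {
  set.seed(7)
  lengths <- 20 * (-log(1 - runif(1000)))^(1 / 1.5) # Weibull(1.5, 20 um)
  fit <- fit_weibull(lengths)
  expect_lt(abs(fit$alpha - 1.5), 0.15)
  expect_lt(abs(fit$a0 - 20), 1.0)

  # invariant to input order
  fit2 <- fit_weibull(rev(sort(lengths)))
  expect_equal(fit2$alpha, fit$alpha)
  expect_equal(fit2$a0, fit$a0)

  # agreement with an independent maximum-likelihood oracle
  mle <- fitdistrplus::fitdist(lengths, "weibull")
  expect_lt(abs(fit$alpha - unname(mle$estimate["shape"])), 0.1)
  expect_lt(abs(fit$a0 - unname(mle$estimate["scale"])), 0.5)
  own_mle <- fit_weibull_mle(lengths)
  expect_equal(own_mle$alpha, unname(mle$estimate["shape"]), tolerance = 1e-3)
  expect_equal(own_mle$a0, unname(mle$estimate["scale"]), tolerance = 1e-3)
})

test_that("degenerate samples are rejected", {
  expect_error(fit_weibull(c(1, 1, 1)), "degenerate")
  expect_error(fit_weibull(c(-1, 2, 3)), "positive")
  expect_error(fit_weibull(5), "at least 2")
})

test_that("hazard behavior follows the shape-parameter taxonomy", {
  a <- seq(1, 40, by = 0.5)
  expect_true(all(diff(weibull_hazard(a, alpha = 2.5, a0 = 10)) > 0))
  expect_equal(diff(range(weibull_hazard(a, alpha = 1, a0 = 10))), 0)
  expect_true(all(diff(weibull_hazard(a, alpha = 0.6, a0 = 10)) < 0))
})

test_that("tidiers and the probability plot expose the fit", {
  fit <- fit_weibull(weibull_quantile(plotting_positions(30), 2, 15))
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "a0"))
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
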