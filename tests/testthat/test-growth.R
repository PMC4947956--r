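p10 <- growth_params(0.816, 1.543, 0.1934)

test_that("closed form hits its endpoints and matches RK4 integration", {
  expect_equal(logistic_growth(p10, 0), 0.816)
  # saturation: far beyond the exponential phase the curve is at x_m
  t_inf <- 45 / p10$mu_m
  expect_equal(logistic_growth(p10, t_inf), 1.543, tolerance = 1e-9)
  # rate-form consistency via fourth-order numeric integration
  tt <- seq(0, 50, by = 0.5)
  ode <- rk4_integrate(function(x) p10$mu_m * x * (1 - x / p10$x_m),
                       x0 = p10$x0, times = tt)
  expect_equal(logistic_growth(p10, tt), ode, tolerance = 1e-6)
  expect_true(all(diff(logistic_growth(p10, tt)) > 0))
  expect_true(all(logistic_growth(p10, tt) <= p10$x_m))
})

test_that("parameter invariants are enforced", {
  expect_error(growth_params(1.6, 1.543, 0.19), class = "ionferm_validation_error")
  expect_error(growth_params(0, 1, 0.1), class = "ionferm_validation_error")
  expect_error(growth_params(0.5, 1, 0), class = "ionferm_validation_error")
  expect_error(logistic_growth(p10, -1), class = "ionferm_validation_error")
})

test_that("growth rate is the logistic quadratic with vertex at x_m/2", {
  expect_equal(growth_rate(p10, p10$x_m), 0)
  expect_equal(growth_rate(p10, 0), 0)
  expect_equal(growth_rate(p10, p10$x_m / 2), p10$mu_m * p10$x_m / 4)
  xs <- seq(0, p10$x_m, length.out = 2001)
  expect_equal(xs[which.max(growth_rate(p10, xs))], p10$x_m / 2,
               tolerance = 1e-3)
  expect_error(growth_rate(p10, p10$x_m + 0.1),
               class = "ionferm_validation_error")
})

test_that("linearization is exact on noise-free curves and logs drops", {
  s <- gen_growth_curve(p10, times = seq(0, 50, 2), noise_sd = 0)
  lin <- linearize_growth(s, p10$x_m)
  expect_equal(attr(lin, "n_dropped"), 0L)
  slopes <- diff(lin$z) / diff(lin$time_h)
  expect_equal(slopes, rep(p10$mu_m, length(slopes)), tolerance = 1e-9)
  # midpoint of the curve transforms to exactly 0
  expect_equal(linearize_growth(growth_series(c(0, 1), c(0.3, p10$x_m / 2)),
                                p10$x_m)$z[2], 0)
  # a plateau row at x_m is excluded with a warning
  s2 <- growth_series(c(0, 10, 20), c(0.5, 1.0, p10$x_m))
  expect_warning(lin2 <- linearize_growth(s2, p10$x_m), "1 row")
  expect_identical(nrow(lin2), 2L)
  expect_error(suppressWarnings(
    linearize_growth(growth_series(c(0, 1), c(2, 3)), x_m = 1)),
    class = "ionferm_validation_error")
})

test_that("linearization inverts generation for random parameter triples", {
  set.seed(31)
  for (i in 1:20) {
    xm <- runif(1, 0.5, 5)
    x0 <- runif(1, 0.05, 0.9) * xm
    mu <- runif(1, 0.02, 0.5)
    p <- growth_params(x0, xm, mu)
    s <- gen_growth_curve(p, times = seq(0, 60, 3), noise_sd = 0)
    fit <- fit_growth_linear(s, x_m = xm)
    expect_equal(fit$mu_m, mu, tolerance = 1e-6)
    expect_equal(fit$x0_implied, x0, tolerance = 1e-6)
  }
})

test_that("linearized fit reproduces the two calibrated culture slopes", {
  s10 <- gen_growth_curve("butyrate10", times = seq(0, 50, 2), noise_sd = 0)
  fit10 <- fit_growth_linear(s10, x_m = 1.543)
  expect_equal(fit10$mu_m, 0.1934, tolerance = 1e-9)
  s12 <- gen_growth_curve("butyrate12", times = seq(0, 50, 2), noise_sd = 0)
  fit12 <- fit_growth_linear(s12, x_m = 1.386)
  expect_equal(fit12$mu_m, 0.1434, tolerance = 1e-9)
  # intercept identity maps back to the generating x0
  expect_equal(fit10$x0_implied, 0.816, tolerance = 1e-9)
})

test_that("noisy linearized fits are unbiased to 2% over 200 replicates", {
  # a design whose readings stay clearly below the plateau: near x_m the
  # transform ln(x/(x_m - x)) amplifies measurement noise without bound
  p <- growth_params(0.08, 1.5, 0.19)
  slopes <- vapply(1:200, function(r) {
    s <- gen_growth_curve(p, times = seq(0, 30, 2), noise_sd = 0.02,
                          seed = 7000 + r)
    suppressWarnings(fit_growth_linear(s, x_m = 1.5)$mu_m)
  }, numeric(1))
  expect_equal(mean(slopes), 0.19, tolerance = 0.02)
})

test_that("Bayesian fit recovers generating parameters and ships envelopes", {
  s <- gen_growth_curve(p10, times = seq(0, 50, 2), noise_sd = 0)
  bf <- fit_growth_bayes(s, x_m = 1.543, n_steps = 1500, seed = 3)
  expect_equal(bf$estimate$mu_m, 0.1934, tolerance = 0.01)
  expect_equal(bf$estimate$x0, 0.816, tolerance = 0.01)
  expect_identical(bf$envelope$levels, c(0.50, 0.90, 0.95, 0.99))
  expect_true(all(bf$sigma_draws > 0))
  expect_identical(nrow(chain_draws(bf$chain, burn = 0)), 1500L)
  # observation envelope is at least as wide as the mean envelope
  expect_true(all(bf$envelope_obs$upper["95%", ] >=
                    bf$envelope$upper["95%", ] - 1e-9))
})

test_that("posterior uncertainty in sigma shrinks with series length", {
  sd_sigma <- vapply(c(25, 200), function(n) {
    s <- gen_growth_curve(p10, times = seq(0, 48, length.out = n),
                          noise_sd = 0.05, seed = 11)
    bf <- suppressWarnings(
      fit_growth_bayes(s, x_m = 1.543, n_steps = 1200, seed = 12))
    sd(bf$sigma_draws)
  }, numeric(1))
  expect_lt(sd_sigma[2], sd_sigma[1])
})
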