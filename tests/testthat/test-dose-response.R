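test_that("lethality probability follows the inverse link on log10 dose", {
  expect_equal(lethality_probability(link_params(0, 0), 37), 0.5)
  expect_equal(lethality_probability(link_params(0, 0, "probit"), 5), 0.5)
  # huge intercept drives the probability to 1
  expect_equal(lethality_probability(link_params(50, 0), 10), 1)
  # strictly increasing in dose when beta1 > 0
  doses <- seq(1, 100, length.out = 50)
  p <- lethality_probability(link_params(-11, 6.9), doses)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > 0 & p < 1))
  for (lk in c("logit", "probit", "cloglog")) {
    pl <- lethality_probability(link_params(-2, 1.5, lk), doses)
    expect_true(all(pl >= 0 & pl <= 1))
    expect_true(all(diff(pl) > 0))
  }
  expect_error(lethality_probability(link_params(0, 1), -5),
               class = "ionferm_validation_error")
  expect_error(lethality_probability(link_params(0, 1), 0),
               class = "ionferm_validation_error")
})

test_that("log-likelihood matches direct arithmetic and handles boundaries", {
  one <- dose_table(10, 1, 1)
  # p = 0.5 on a single Bernoulli death
  expect_equal(dose_log_likelihood(link_params(0, 0), one), log(0.5))
  tab <- table1_dose_response()
  # at (0,0) every p is 0.5: closed form sum(lchoose) + log(0.5) * sum(n)
  expect_equal(dose_log_likelihood(link_params(0, 0), tab),
               sum(lchoose(tab$n, tab$deaths)) + log(0.5) * sum(tab$n))
  # appending an empty group changes nothing
  tab2 <- dose_table(c(tab$dose, 7), c(tab$n, 0), c(tab$deaths, 0))
  expect_equal(dose_log_likelihood(link_params(0, 0), tab2),
               dose_log_likelihood(link_params(0, 0), tab))
  # p numerically 0 with observed deaths: -Inf, not an error
  expect_identical(dose_log_likelihood(link_params(-1000, 0), one), -Inf)
  expect_identical(dose_deviance(link_params(-1000, 0), one), Inf)
})

test_that("deviance is -2 log likelihood and minimal at the MLE", {
  one <- dose_table(10, 1, 1)
  expect_equal(dose_deviance(link_params(0, 0), one), -2 * log(0.5))
  tab <- table1_dose_response()
  expect_equal(dose_deviance(link_params(0, 0), tab),
               -2 * (sum(lchoose(tab$n, tab$deaths)) + log(0.5) * sum(tab$n)))
  fit <- fit_dose_response(tab)
  d_mle <- dose_deviance(fit$params, tab)
  set.seed(42)
  for (i in 1:20) {
    other <- link_params(coef(fit)[1] + rnorm(1, 0, 0.5),
                         coef(fit)[2] + rnorm(1, 0, 0.5))
    expect_gte(dose_deviance(other, tab), d_mle)
  }
})

test_that("log-likelihood is concave in (beta0, beta1) for the logit link", {
  tab <- table1_dose_response()
  set.seed(7)
  for (i in 1:25) {
    a <- c(rnorm(1, -11, 3), rnorm(1, 7, 3))
    b <- c(rnorm(1, -11, 3), rnorm(1, 7, 3))
    mid <- (a + b) / 2
    ll <- function(th) dose_log_likelihood(link_params(th[1], th[2]), tab)
    expect_gte(ll(mid), (ll(a) + ll(b)) / 2 - 1e-8)
  }
})

test_that("two-point fit solves the logit equations exactly", {
  # log-doses -1 and +1 with exact lethal fractions 1/4 and 3/4:
  # beta0 = 0, beta1 = logit(0.75)
  tab <- dose_table(c(0.1, 10), c(4000, 4000), c(1000, 3000))
  fit <- fit_dose_response(tab)
  expect_equal(unname(coef(fit)[1]), 0, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[2]), log(3), tolerance = 1e-6)
})

test_that("MLE on the packaged table matches the fine-grid oracle", {
  tab <- table1_dose_response()
  fit <- fit_dose_response(tab)
  oracle <- grid_mle_oracle(tab)
  expect_equal(unname(coef(fit)), oracle, tolerance = 1e-3)
  # fitted curve at 90 Gy agrees with the oracle maximizer's curve
  p_oracle <- plogis(oracle[1] + oracle[2] * log10(90))
  expect_equal(unname(predict(fit, 90)), p_oracle, tolerance = 1e-4)
})

test_that("probit and cloglog links fit and match their grid oracles", {
  tab <- table1_dose_response()
  for (lk in c("probit", "cloglog")) {
    fit <- fit_dose_response(tab, link = lk)
    oracle <- grid_mle_oracle(tab, link = lk)
    expect_equal(unname(coef(fit)), oracle, tolerance = 5e-3)
  }
})

test_that("complete separation is flagged as a named error", {
  tab <- dose_table(c(10, 20, 40, 80), rep(1000, 4), c(0, 0, 1000, 1000))
  suppressWarnings(
    expect_error(fit_dose_response(tab), class = "ionferm_separation_error"))
})

test_that("degenerate tables are rejected with validation errors", {
  expect_error(dose_table(c(10, 10), c(5, 5), c(1, 2)),
               class = "ionferm_validation_error")   # duplicate dose
  expect_error(dose_table(10, 5, 6), class = "ionferm_validation_error")
  expect_error(fit_dose_response(dose_table(c(10, 20), c(100, 100), c(0, 0))),
               class = "ionferm_validation_error")
})

test_that("MLE recovers simulated truth within 3 SE in at least 95% of runs", {
  truth <- link_params(-11.1, 6.88)
  ok <- 0L
  for (r in 1:200) {
    tab <- gen_dose_response(truth, n_per_dose = rep(1e4, 16), seed = 5000 + r)
    fit <- fit_dose_response(tab)
    se <- sqrt(diag(vcov(fit)))
    dev <- abs(coef(fit) - c(truth$beta0, truth$beta1)) / se
    if (all(dev < 3)) ok <- ok + 1L
  }
  expect_gte(ok / 200, 0.95)
})

test_that("posterior predictive p is seeded and calibrated", {
  tab <- table1_dose_response()
  # single-draw chain: p is 0 or 1 and reproducible
  single <- matrix(c(-11.1, 6.88), 1, 2)
  p1 <- posterior_predictive_p(single, tab, seed = 11)
  expect_true(p1 %in% c(0, 1))
  expect_identical(p1, posterior_predictive_p(single, tab, seed = 11))

  # data simulated from the model: p away from the extremes on average
  truth <- link_params(-11.1, 6.88)
  ps <- vapply(1:50, function(i) {
    sim <- gen_dose_response(truth, n_per_dose = rep(500, 16), seed = 1000 + i)
    ch <- dose_posterior_chain(sim, n_steps = 1000, seed = 2000 + i)
    posterior_predictive_p(ch, sim, seed = 3000 + i)
  }, numeric(1))
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.8)

  # dose-independent deaths against a strong dose-signal chain: p near 0
  sim <- gen_dose_response(truth, n_per_dose = rep(5000, 16), seed = 9)
  flat <- dose_table(sim$dose, sim$n, round(sim$n * 0.5))
  ch <- dose_posterior_chain(sim, n_steps = 1000, seed = 10)
  expect_lt(posterior_predictive_p(ch, flat, seed = 11), 0.05)
})
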