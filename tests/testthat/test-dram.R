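std_normal_lp <- function(th) -0.5 * sum(th^2)

test_that("fixed seeds give bit-identical chains", {
  a <- run_dram(std_normal_lp, 0, n_steps = 300, seed = 42)
  b <- run_dram(std_normal_lp, 0, n_steps = 300, seed = 42)
  expect_identical(a$draws, b$draws)
  c <- run_dram(std_normal_lp, 0, n_steps = 300, seed = 43)
  expect_false(identical(a$draws, c$draws))
  # with an error-variance chain too
  ss <- function(th) sum((c(1, 2, 3) - th)^2)
  d1 <- run_dram(function(th, s2) -ss(th) / (2 * s2) - 1.5 * log(s2),
                 2, n_steps = 200, seed = 1, ss_fn = ss, n_obs = 3)
  d2 <- run_dram(function(th, s2) -ss(th) / (2 * s2) - 1.5 * log(s2),
                 2, n_steps = 200, seed = 1, ss_fn = ss, n_obs = 3)
  expect_identical(d1$draws, d2$draws)
  expect_identical(d1$s2chain, d2$s2chain)
  expect_true(all(d1$s2chain > 0))
})

test_that("chain dimensions and study defaults are as documented", {
  ch <- run_dram(std_normal_lp, c(0, 0), n_steps = 150, seed = 5)
  expect_identical(dim(ch$draws), c(150L, 2L))
  expect_true(ch$acceptance_rate > 0 && ch$acceptance_rate <= 1)
  expect_identical(eval(formals(run_dram)$n_steps), 5000)
  expect_identical(eval(formals(repeat_runs)$n_repeats), 500)
  expect_error(run_dram(std_normal_lp, 0, n_steps = 50),
               class = "ionferm_validation_error")
})

test_that("bad posteriors are handled: NaN aborts, -Inf at init rejected", {
  expect_error(run_dram(function(th) NaN * th, 1, n_steps = 100, seed = 1),
               "NaN")
  expect_error(run_dram(function(th) -Inf, 0, n_steps = 100, seed = 1),
               class = "ionferm_validation_error")
  # -Inf proposals act as rejections: chain stays within the support
  lp <- function(th) if (th < 0) -Inf else -th
  ch <- run_dram(lp, 1, n_steps = 500, seed = 3)
  expect_true(all(ch$draws >= 0))
})

test_that("DRAM recovers standard-Gaussian moments over 50 seeded runs", {
  means <- vars <- numeric(50)
  for (s in 1:50) {
    ch <- run_dram(std_normal_lp, 0.5, n_steps = 5000, seed = s)
    d <- chain_draws(ch)[, 1]
    means[s] <- mean(d)
    vars[s] <- var(d)
  }
  expect_lt(abs(mean(means)), 0.05)
  expect_lt(abs(mean(vars) - 1), 0.1)
})

test_that("DRAM recovers a correlated 2D Gaussian to 5%", {
  S <- matrix(c(1, 0.8, 0.8, 1), 2)
  Si <- solve(S)
  ch <- run_dram(function(th) -0.5 * drop(th %*% Si %*% th), c(0, 0),
                 n_steps = 20000, seed = 7)
  d <- chain_draws(ch)
  expect_lt(max(abs(colMeans(d))), 0.05)
  expect_equal(unname(cov(d)), S, tolerance = 0.05)
})

test_that("error-variance draws follow the conjugate inverse-gamma", {
  set.seed(1)
  draws <- replicate(1e5, sample_error_variance(500, 1000))
  # vague prior, large n: posterior mean approaches SS / n
  expect_equal(mean(draws), 500 / 1000, tolerance = 0.02)
  expect_true(all(draws > 0))
  # zero residual SS with a vague prior collapses toward the prior scale
  small <- replicate(1000, sample_error_variance(0, 50))
  expect_lt(median(small), 0.01)
  expect_error(sample_error_variance(-1, 10),
               class = "ionferm_validation_error")
})

test_that("predictive envelopes are degenerate for constant chains and nested", {
  const <- matrix(rep(c(1, 2), each = 50), 50, 2)
  env <- predictive_envelope(const, function(th, g) th[1] + th[2] * g,
                             grid = 1:10, seed = 1)
  expect_equal(env$lower, env$upper, tolerance = 1e-12)
  ch <- run_dram(std_normal_lp, 0, n_steps = 2000, seed = 2)
  env <- predictive_envelope(ch, function(th, g) th[1] * g, grid = seq(0, 5),
                             seed = 3)
  for (i in seq_len(length(env$levels) - 1)) {
    expect_true(all(env$lower[i + 1, ] <= env$lower[i, ] + 1e-12))
    expect_true(all(env$upper[i + 1, ] >= env$upper[i, ] - 1e-12))
  }
  expect_identical(eval(formals(predictive_envelope)$levels),
                   c(0.50, 0.90, 0.95, 0.99))
  expect_error(predictive_envelope(matrix(numeric(0), 0, 2),
                                   function(th, g) g, 1:3),
               class = "ionferm_validation_error")
})

test_that("diagnostics report exact moments and degenerate chains", {
  const <- structure(list(draws = matrix(2.5, 100, 1), s2chain = NULL,
                          acceptance_rate = 1, n_steps = 100, seed = 1,
                          burn_frac = 0), class = "dram_chain")
  d <- chain_diagnostics(const)
  expect_equal(unname(d$summary[1, "sd"]), 0)
  expect_equal(unname(d$summary[1, "mean"]), 2.5)
  ch <- run_dram(std_normal_lp, 0, n_steps = 1000, seed = 9)
  d <- chain_diagnostics(ch, burn = 0)
  expect_equal(unname(d$summary[1, "mean"]), mean(ch$draws[, 1]))
})

test_that("binomial posterior mean agrees with the MLE location", {
  tab <- table1_dose_response()
  fit <- fit_dose_response(tab)
  ch <- dose_posterior_chain(tab, fit, n_steps = 5000, seed = 21)
  post <- colMeans(chain_draws(ch))
  post_sd <- apply(chain_draws(ch), 2, sd)
  expect_true(all(abs(post - coef(fit)) < 3 * post_sd))
})

test_that("repeat-run facility pools per-run posterior means", {
  m <- repeat_runs(function(s) run_dram(std_normal_lp, 0, n_steps = 400,
                                        seed = s),
                   n_repeats = 10, seed = 100)
  expect_identical(dim(m), c(10L, 1L))
  expect_lt(abs(mean(m)), 0.3)
})
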