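test_that("all generators are reproducible under a fixed seed", {
  pars <- link_params(-11, 6.9)
  expect_identical(gen_dose_response(pars, seed = 5),
                   gen_dose_response(pars, seed = 5))
  expect_identical(gen_growth_curve("butyrate10", seed = 5),
                   gen_growth_curve("butyrate10", seed = 5))
  expect_identical(gen_screening_matrix(n_strains = 30, seed = 5),
                   gen_screening_matrix(n_strains = 30, seed = 5))
  expect_identical(gen_ph_trajectory("pH5.0", seed = 5),
                   gen_ph_trajectory("pH5.0", seed = 5))
  expect_identical(gen_fermentation("pH5.0", seed = 5),
                   gen_fermentation("pH5.0", seed = 5))
  expect_false(identical(gen_fermentation("pH5.0", seed = 5),
                         gen_fermentation("pH5.0", seed = 6)))
})

test_that("dose-response generation respects the binomial structure", {
  # degenerate probability 1: every cell dies
  all_die <- gen_dose_response(link_params(100, 0), seed = 1)
  expect_identical(all_die$deaths, all_die$n)
  # defaults reproduce the 16-dose experimental layout
  expect_identical(all_die$dose, seq(15, 90, by = 5))
  expect_identical(sum(all_die$n), 96600)
  expect_error(gen_dose_response(link_params(0, 1), doses = c(-1, 10),
                                 n_per_dose = c(5, 5)),
               class = "ionferm_validation_error")
  expect_error(gen_dose_response(link_params(0, 1), doses = c(5, 10),
                                 n_per_dose = 5),
               class = "ionferm_validation_error")
})

test_that("empirical lethality converges to the model curve", {
  pars <- link_params(-11.1, 6.88)
  doses <- seq(15, 90, by = 5)
  p <- lethality_probability(pars, doses)
  n <- 1e5
  se <- sqrt(p * (1 - p) / n)
  ok <- vapply(1:100, function(r) {
    tab <- gen_dose_response(pars, doses, rep(n, length(doses)),
                             seed = 8000 + r)
    all(abs(tab$deaths / tab$n - p) <= 4 * se)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("noise-free growth curves equal the closed form exactly", {
  p <- growth_params(0.7, 2.1, 0.25)
  s <- gen_growth_curve(p, times = seq(0, 40, 2), noise_sd = 0)
  expect_identical(s$biomass_gL, logistic_growth(p, s$time_h))
  expect_true(all(gen_growth_curve(p, noise_sd = 5, seed = 2)$biomass_gL >= 0))
  # named scenarios carry the calibrated parameter triples
  p10 <- growth_scenario("butyrate10")
  expect_equal(c(p10$x0, p10$x_m, p10$mu_m), c(0.816, 1.543, 0.1934))
  p12 <- growth_scenario("butyrate12")
  expect_equal(c(p12$x_m, p12$mu_m), c(1.386, 0.1434))
  expect_error(gen_growth_curve(p, times = c(3, 2, 1), noise_sd = 0),
               class = "ionferm_validation_error")
})

test_that("screening sampler has the requested Gaussian structure", {
  m <- gen_screening_matrix(n_strains = 2e4, mean = rep(0, 4),
                            covariance = diag(4), n_outliers = 0, seed = 3)
  S <- cov(m$ratings)
  # elementwise within 3 standard errors of the identity
  se_diag <- sqrt(2 / 2e4)
  se_off <- sqrt(1 / 2e4)
  expect_true(all(abs(diag(S) - 1) <= 3 * se_diag))
  off <- S[upper.tri(S)]
  expect_true(all(abs(off) <= 3 * se_off))
  expect_error(gen_screening_matrix(covariance = matrix(c(1, 2, 2, 1), 2),
                                    mean = c(0, 0)),
               class = "ionferm_validation_error")   # not positive definite
})

test_that("pH skeletons hit the calibrated start, peak and terminal values", {
  s5 <- gen_ph_trajectory("pH5.0", process_noise = FALSE, meas_noise = FALSE)
  expect_identical(s5$pH, s5$latent_pH)          # noise off: observed = latent
  expect_equal(s5$latent_pH[1], 5.0)
  expect_equal(tail(s5$latent_pH, 1), 4.2)
  expect_identical(diff(s5$time_h), rep(2, 60))  # 2-h sampling over 120 h
  # one transient rise peaking at 42 h
  interior <- s5$latent_pH[s5$time_h >= 20 & s5$time_h <= 60]
  t_int <- s5$time_h[s5$time_h >= 20 & s5$time_h <= 60]
  expect_equal(t_int[which.max(interior)], 42)
  s45 <- gen_ph_trajectory("pH4.5", process_noise = FALSE, meas_noise = FALSE)
  expect_equal(s45$latent_pH[1], 4.5)
  expect_equal(s45$latent_pH[1] - tail(s45$latent_pH, 1), 0.4)
  interior <- s45$latent_pH[s45$time_h >= 10 & s45$time_h <= 50]
  t_int <- s45$time_h[s45$time_h >= 10 & s45$time_h <= 50]
  expect_equal(t_int[which.max(interior)], 28)
})

test_that("fermentation channels keep their shape constraints for any seed", {
  for (seed in 1:20) {
    s <- gen_fermentation("pH5.0", seed = seed)
    expect_true(all(diff(s$glucose_gL) <= 1e-12))
    expect_true(all(diff(s$gas) >= -1e-12))
    expect_true(all(s$glucose_gL >= 0))
  }
  s <- gen_fermentation("pH4.5", noise = FALSE)
  expect_true(all(diff(s$butyrate_gL) > 0))
  expect_identical(tail(s$time_h, 1), 110)
  expect_identical(s$glucose_gL[1], 60)
  s5 <- gen_fermentation("pH5.0", noise = FALSE)
  expect_identical(tail(s5$time_h, 1), 200)
  expect_identical(s5$glucose_gL[1], 150)
})
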