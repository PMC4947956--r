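#' Scenario configuration for the synthetic-data generators
#'
#' A named, seeded parameter bundle consumed by the series generators.
#' Identical `(name, parameters, seed)` triples produce byte-identical
#' output. Built-in scenario names carry calibrated defaults
#' (see [gen_ph_trajectory()] and [gen_fermentation()]); parameters given
#' here override them.
#'
#' @param name scenario label, e.g. `"pH5.0"`.
#' @param parameters named list of numeric overrides.
#' @param seed non-negative integer seed, or `NULL`.
#' @param noise named logical noise flags (e.g. `process`, `measurement`).
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(name, parameters = list(), seed = NULL,
                            noise = c(process = TRUE, measurement = TRUE)) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.null(seed)) check_number(seed, "seed", lower = 0)
  structure(list(name = name, parameters = parameters, seed = seed,
                 noise = noise),
            class = "scenario_config")
}

# Table of per-dose irradiation totals used as generator defaults:
# 16 doses 15-90 Gy with the recorded numbers of cells at risk.
default_doses <- function() seq(15, 90, by = 5)
default_n_per_dose <- function() {
  c(50, 62, 55, 59, 65, 60, 57, 55, 58, 60, 56, 67, 63, 61, 68, 70) * 100
}

#' Simulate a binomial dose-response table
#'
#' Draws per-dose death counts `deaths_i ~ Binomial(n_i, p(dose_i))` with
#' `p` given by [lethality_probability()]. Defaults reproduce the shape
#' of the packaged 16-dose irradiation experiment (doses 15-90 Gy and the
#' recorded per-dose totals).
#'
#' @param params a [link_params()] pair defining the lethality curve.
#' @param doses strictly positive doses in Gy.
#' @param n_per_dose positive cell totals, one per dose.
#' @param seed optional integer seed.
#' @return A [dose_table()].
#' @export
gen_dose_response <- function(params, doses = default_doses(),
                              n_per_dose = default_n_per_dose(),
                              seed = NULL) {
  if (length(doses) != length(n_per_dose))
    abort_validation("doses and n_per_dose must have equal length")
  if (any(doses <= 0)) abort_validation("doses must be strictly positive")
  if (any(n_per_dose < 1)) abort_validation("n_per_dose must be positive")
  p <- lethality_probability(params, doses)
  with_seed(seed,
    dose_table(doses, n_per_dose,
               stats::rbinom(length(doses), n_per_dose, p)))
}

#' Built-in growth scenarios
#'
#' Parameter triples of the two calibrated batch-growth conditions:
#' cultures supplemented with 10.0 g/L butyric acid
#' (`x0 = 0.816, x_m = 1.543, mu_m = 0.1934`) and with 12.0 g/L
#' (`x0 = 0.553, x_m = 1.386, mu_m = 0.1434`).
#'
#' @param name `"butyrate10"` or `"butyrate12"`.
#' @return A [growth_params()] triple.
#' @export
growth_scenario <- function(name = c("butyrate10", "butyrate12")) {
  switch(match.arg(name),
         butyrate10 = growth_params(x0 = 0.816, x_m = 1.543, mu_m = 0.1934),
         butyrate12 = growth_params(x0 = 0.553, x_m = 1.386, mu_m = 0.1434))
}

#' Simulate a logistic growth series
#'
#' Evaluates the closed-form logistic curve and adds i.i.d. zero-mean
#' Gaussian measurement noise, truncated at zero. `noise_sd = 0` returns
#' the deterministic skeleton exactly.
#'
#' @param growth a [growth_params()] triple or a [growth_scenario()] name.
#' @param times non-negative, increasing sampling times in hours
#'   (default 0-50 h every 2 h).
#' @param noise_sd measurement noise sd in g/L, `>= 0` (default 0.02).
#' @param seed optional integer seed.
#' @return A [growth_series()].
#' @export
gen_growth_curve <- function(growth, times = seq(0, 50, by = 2),
                             noise_sd = 0.02, seed = NULL) {
  if (is.character(growth)) growth <- growth_scenario(growth)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (any(times < 0) || any(diff(times) <= 0))
    abort_validation("times must be non-negative and increasing")
  x <- logistic_growth(growth, times)
  if (noise_sd > 0)
    x <- with_seed(seed, pmax(0, x + stats::rnorm(length(x), 0, noise_sd)))
  growth_series(times, x, noise_sd = noise_sd)
}

#' Default screening-population covariance
#'
#' Covariance of the four rating variables (maximum biomass, butyrate,
#' hydrogen, B/A ratio) used by [gen_screening_matrix()]. Its correlation
#' structure is built from eigenvalue fractions
#' `(0.31, 0.31, 0.31, 0.07)`, so an inverse-variance weighted PCA of the
#' population carries 62% of variance on the first two components and
#' 93% on the first three.
#'
#' @param sds per-variable standard deviations.
#' @return A 4x4 symmetric positive-definite matrix.
#' @export
default_screening_covariance <- function(sds = c(1.0, 1.5, 0.8, 1.2)) {
  H <- matrix(c(1, 1, 1, 1,
                1, -1, 1, -1,
                1, 1, -1, -1,
                1, -1, -1, 1), 4, 4) / 2
  corr <- H %*% diag(c(0.31, 0.31, 0.31, 0.07) * 4) %*% t(H)
  cov <- diag(sds) %*% corr %*% diag(sds)
  dimnames(cov) <- rep(list(c("max_biomass", "butyrate", "hydrogen",
                              "ba_ratio")), 2)
  cov
}

#' Simulate a mutant-strain screening matrix
#'
#' Multivariate-Gaussian ratings over (maximum biomass, butyrate,
#' hydrogen, B/A ratio) for `n_strains` screened mutants, with a handful
#' of rows shifted to act as outliers. Default outlier positions follow
#' the strain numbering convention of the screening campaign
#' (rows 8, 78, 150, 203, 221, 278, 323 when they fit).
#'
#' @param n_strains number of strains (default 329).
#' @param mean rating mean vector.
#' @param covariance symmetric positive-definite rating covariance
#'   (default [default_screening_covariance()]).
#' @param n_outliers number of shifted rows (default 7).
#' @param outlier_shift shift added to outlier rows (default 4 sd per
#'   variable, hydrogen shifted down).
#' @param outlier_rows optional explicit outlier row indices.
#' @param seed optional integer seed; a fixed seed gives an identical
#'   matrix across calls.
#' @return A [screening_matrix()] with attribute `"outlier_rows"`.
#' @export
gen_screening_matrix <- function(n_strains = 329,
                                 mean = c(7.0, 6.5, 6.0, 7.5),
                                 covariance = default_screening_covariance(),
                                 n_outliers = 7,
                                 outlier_shift = NULL,
                                 outlier_rows = NULL,
                                 seed = NULL) {
  check_number(n_strains, "n_strains", lower = 5)
  p <- length(mean)
  covariance <- as.matrix(covariance)
  if (!isSymmetric(covariance, tol = 1e-8))
    abort_validation("covariance must be symmetric")
  ch <- tryCatch(chol(covariance), error = function(e) NULL)
  if (is.null(ch))
    abort_validation("covariance must be positive definite")
  if (is.null(outlier_shift)) {
    s <- sqrt(diag(covariance))
    outlier_shift <- 4 * s * c(1, 1, -1, 1)[seq_len(p)]
  }
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_strains * p), n_strains, p)
    ratings <- sweep(Z %*% ch, 2, mean, `+`)
    if (n_outliers > 0) {
      canonical <- c(8, 78, 150, 203, 221, 278, 323)
      if (is.null(outlier_rows)) {
        outlier_rows <- if (n_outliers <= length(canonical) &&
                            n_strains >= max(canonical[seq_len(n_outliers)]))
          canonical[seq_len(n_outliers)]
        else sample.int(n_strains, n_outliers)
      }
      ratings[outlier_rows, ] <-
        sweep(ratings[outlier_rows, , drop = FALSE], 2, outlier_shift, `+`)
    } else outlier_rows <- integer(0)
    colnames(ratings) <- colnames(covariance)
    out <- screening_matrix(ratings,
                            strain_id = sprintf("FS-ZKJ-D80-85-%d",
                                                seq_len(n_strains)))
    attr(out, "outlier_rows") <- outlier_rows
    out
  })
}

ph_scenario_defaults <- function(name) {
  switch(name,
    "pH5.0" = list(knot_t = c(0, 30, 42, 120), knot_pH = c(5.0, 4.60, 4.75, 4.20),
                   horizon = 120, dt = 2, process_sd = 0.01, meas_sd = 0.05),
    "pH4.5" = list(knot_t = c(0, 20, 28, 120), knot_pH = c(4.50, 4.25, 4.40, 4.10),
                   horizon = 120, dt = 2, process_sd = 0.01, meas_sd = 0.05),
    abort_validation(sprintf("unknown pH scenario '%s'", name)))
}

#' Simulate a serum-bottle pH trajectory
#'
#' The latent pH follows a piecewise-linear skeleton -- an acidogenic
#' decline interrupted by one transient rise as acids are converted to
#' neutral solvents -- plus optional random-walk process noise;
#' observations add zero-mean Gaussian measurement error. Built-in
#' scenarios: `"pH5.0"` (start 5.0, transient peak at 42 h, terminal
#' 4.2 over 120 h) and `"pH4.5"` (start 4.5, peak at 28 h, total drop
#' 0.4). Sampling every 2 h.
#'
#' @param scenario scenario name or a [scenario_config()].
#' @param seed optional integer seed (overrides the config's).
#' @param process_noise add random-walk process noise to the latent pH?
#' @param meas_noise add Gaussian measurement noise to the observations?
#' @return A [ph_series()] with both observed and latent pH.
#' @examples
#' s <- gen_ph_trajectory("pH5.0", seed = 1, process_noise = FALSE,
#'                        meas_noise = FALSE)
#' tail(s$latent_pH, 1)  # 4.2
#' @export
gen_ph_trajectory <- function(scenario = "pH5.0", seed = NULL,
                              process_noise = TRUE, meas_noise = TRUE) {
  if (inherits(scenario, "scenario_config")) {
    cfg <- scenario
    if (is.null(seed)) seed <- cfg$seed
    process_noise <- isTRUE(cfg$noise[["process"]]) && process_noise
    meas_noise <- isTRUE(cfg$noise[["measurement"]]) && meas_noise
  } else cfg <- scenario_config(scenario)
  par <- utils::modifyList(ph_scenario_defaults(cfg$name), cfg$parameters)
  tt <- seq(0, par$horizon, by = par$dt)
  trend <- stats::approx(par$knot_t, par$knot_pH, xout = tt, rule = 2)$y
  with_seed(seed, {
    latent <- trend
    if (process_noise && par$process_sd > 0)
      latent <- latent + c(0, cumsum(stats::rnorm(length(tt) - 1, 0,
                                                  par$process_sd)))
    observed <- latent
    if (meas_noise && par$meas_sd > 0)
      observed <- observed + stats::rnorm(length(tt), 0, par$meas_sd)
    ph_series(tt, pmin(pmax(observed, 0.01), 13.99),
              latent_pH = pmin(pmax(latent, 0.01), 13.99))
  })
}

ferment_scenario_defaults <- function(name) {
  switch(name,
    # endpoints calibrated to the recorded final titres: butyrate
    # 57.63 g/L with B/A 6.2 at pH 5.0; B/A 2.9 at pH 4.5
    "pH5.0" = list(horizon = 200, dt = 2, glucose0 = 150,
                   butyrate_final = 57.63, ba_final = 6.2,
                   but_mid = 50, but_rate = 0.08,
                   ace_mid = 30, ace_rate = 0.10,
                   glucose_consumed = 140,
                   od0 = 0.05, od_max = 3.9, od_mid = 20, od_rate = 0.15,
                   gas_per_acid = 1.5, noise_cv = 0.02),
    "pH4.5" = list(horizon = 110, dt = 2, glucose0 = 60,
                   butyrate_final = 2.9 * 8.0, ba_final = 2.9,
                   but_mid = 45, but_rate = 0.08,
                   ace_mid = 28, ace_rate = 0.10,
                   glucose_consumed = 55,
                   od0 = 0.05, od_max = 2.8, od_mid = 22, od_rate = 0.15,
                   gas_per_acid = 1.5, noise_cv = 0.02),
    abort_validation(sprintf("unknown fermentation scenario '%s'", name)))
}

# logistic-in-time ramp normalized to 0 at t = 0 and 1 at t = horizon
saturating_ramp <- function(t, mid, rate, horizon) {
  f <- stats::plogis(rate * (t - mid))
  f0 <- stats::plogis(rate * (0 - mid))
  fT <- stats::plogis(rate * (horizon - mid))
  (f - f0) / (fT - f0)
}

#' Simulate a batch fermentation time series
#'
#' Butyrate and acetate follow saturating logistic-in-time production
#' curves normalized so the final sample equals the calibrated endpoint
#' exactly; glucose decreases in proportion to total acid formed; OD600
#' follows logistic growth; cumulative gas tracks acid production.
#' Built-in scenarios: `"pH5.0"` (150 g/L glucose, 200 h, final butyrate
#' 57.63 g/L, final B/A 6.2) and `"pH4.5"` (60 g/L glucose, 110 h, final
#' B/A 2.9). Optional multiplicative Gaussian noise never breaks channel
#' monotonicity: glucose and gas noise act on per-step increments,
#' truncated at zero.
#'
#' @param scenario scenario name or a [scenario_config()].
#' @param seed optional integer seed.
#' @param noise add measurement noise? `FALSE` returns the deterministic
#'   skeleton.
#' @return A [fermentation_series()].
#' @examples
#' summarize_fermentation(gen_fermentation("pH5.0", noise = FALSE))
#' @export
gen_fermentation <- function(scenario = "pH5.0", seed = NULL, noise = TRUE) {
  if (inherits(scenario, "scenario_config")) {
    cfg <- scenario
    if (is.null(seed)) seed <- cfg$seed
    noise <- noise && any(cfg$noise)
  } else cfg <- scenario_config(scenario)
  par <- utils::modifyList(ferment_scenario_defaults(cfg$name), cfg$parameters)
  tt <- seq(0, par$horizon, by = par$dt)
  but <- par$butyrate_final *
    saturating_ramp(tt, par$but_mid, par$but_rate, par$horizon)
  ace <- (par$butyrate_final / par$ba_final) *
    saturating_ramp(tt, par$ace_mid, par$ace_rate, par$horizon)
  total_acid <- but + ace
  consumption <- par$glucose_consumed * total_acid / tail_value(total_acid)
  glu <- par$glucose0 - consumption
  od <- par$od0 + (par$od_max - par$od0) *
    saturating_ramp(tt, par$od_mid, par$od_rate, par$horizon)
  gas <- par$gas_per_acid * total_acid
  if (noise) {
    cv <- par$noise_cv
    with_seed(seed, {
      n <- length(tt)
      but <- pmax(0, but + stats::rnorm(n, 0, cv * max(but)))
      ace <- pmax(0, ace + stats::rnorm(n, 0, cv * max(ace)))
      od <- pmax(0, od + stats::rnorm(n, 0, cv * max(od)))
      # keep glucose non-increasing / gas non-decreasing for any seed:
      # jitter the per-step increments and truncate them at zero
      dg <- pmax(0, diff(consumption) * (1 + stats::rnorm(n - 1, 0, cv * 5)))
      glu <- pmax(0, par$glucose0 - cumsum(c(0, dg)))
      dgas <- pmax(0, diff(gas) * (1 + stats::rnorm(n - 1, 0, cv * 5)))
      gas <- cumsum(c(gas[1], dgas))
      fermentation_series(tt, but, ace, glu, od, gas)
    })
  } else fermentation_series(tt, but, ace, glu, od, gas)
}

#' Materialize all default synthetic fixtures
#'
#' Writes every default scenario of every generator, plus a copy of the
#' packaged 16-dose irradiation table, as headered CSV files.
#'
#' @param dir output directory (created if needed).
#' @param seed base integer seed; per-file seeds are derived from it.
#' @return Invisibly, the vector of files written.
#' @export
write_fixtures <- function(dir, seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  tab1 <- table1_dose_response()
  mle <- fit_dose_response(tab1)
  files <- c(
    table1_dose_response = {
      write_input_table(tab1, path("table1_dose_response.csv"))
    },
    dose_response_sim = write_input_table(
      gen_dose_response(mle$params, seed = seed),
      path("dose_response_sim.csv")),
    growth_butyrate10 = write_input_table(
      gen_growth_curve("butyrate10", seed = seed + 1),
      path("growth_butyrate10.csv")),
    growth_butyrate12 = write_input_table(
      gen_growth_curve("butyrate12", seed = seed + 2),
      path("growth_butyrate12.csv")),
    screening_default = write_input_table(
      gen_screening_matrix(seed = seed + 3),
      path("screening_default.csv")),
    ph_5.0 = write_input_table(gen_ph_trajectory("pH5.0", seed = seed + 4),
                               path("ph_pH5.0.csv")),
    ph_4.5 = write_input_table(gen_ph_trajectory("pH4.5", seed = seed + 5),
                               path("ph_pH4.5.csv")),
    fermentation_pH5.0 = write_input_table(
      gen_fermentation("pH5.0", seed = seed + 6),
      path("fermentation_pH5.0.csv")),
    fermentation_pH4.5 = write_input_table(
      gen_fermentation("pH4.5", seed = seed + 7),
      path("fermentation_pH4.5.csv")))
  invisible(files)
}
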