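#' Logistic growth parameters
#'
#' Parameter triple of the logistic batch-growth model: initial biomass
#' `x0`, maximum attainable biomass `x_m` (both g/L dry cell weight) and
#' maximum specific growth rate `mu_m` (1/h).
#'
#' @param x0 initial biomass, `0 < x0 < x_m`.
#' @param x_m carrying capacity (maximum attainable biomass).
#' @param mu_m maximum specific growth rate, `> 0`.
#' @return A list of class `"growth_params"`.
#' @export
growth_params <- function(x0, x_m, mu_m) {
  check_number(x0, "x0", lower = 0, strict_lower = TRUE)
  check_number(x_m, "x_m", lower = 0, strict_lower = TRUE)
  check_number(mu_m, "mu_m", lower = 0, strict_lower = TRUE)
  if (x0 >= x_m) abort_validation("x0 must be strictly below x_m")
  structure(list(x0 = x0, x_m = x_m, mu_m = mu_m), class = "growth_params")
}

#' Closed-form logistic growth curve
#'
#' Biomass at time `t` under logistic kinetics:
#' `x(t) = x_m / (1 + ((x_m - x0)/x0) * exp(-mu_m t))`, the solution of
#' `dx/dt = mu_m x (1 - x/x_m)` with `x(0) = x0`. Strictly increasing and
#' bounded above by `x_m`.
#'
#' @param params a [growth_params()] triple.
#' @param t time(s) in hours, `>= 0`.
#' @return Biomass in g/L, one value per time.
#' @examples
#' logistic_growth(growth_params(0.816, 1.543, 0.1934), t = c(0, 25, 50))
#' @export
logistic_growth <- function(params, t) {
  stopifnot(inherits(params, "growth_params"))
  if (any(t < 0)) abort_validation("t must be non-negative")
  params$x_m / (1 + (params$x_m - params$x0) / params$x0 *
                  exp(-params$mu_m * t))
}

#' Logistic growth rate
#'
#' Instantaneous biomass production rate `mu_m x (1 - x/x_m)`, zero at
#' `x = 0` and `x = x_m` and maximal at `x = x_m / 2`.
#'
#' @param params a [growth_params()] triple.
#' @param x biomass in `[0, x_m]`.
#' @return Growth rate(s) in g/L per hour.
#' @export
growth_rate <- function(params, x) {
  stopifnot(inherits(params, "growth_params"))
  if (any(x < 0 | x > params$x_m))
    abort_validation("x must lie in [0, x_m]")
  params$mu_m * x * (1 - x / params$x_m)
}

#' Growth time series
#'
#' @param time hours, strictly increasing.
#' @param biomass g/L dry cell weight, non-negative.
#' @param noise_sd optional known measurement noise sd (g/L), recorded as
#'   an attribute.
#' @return A `data.frame` of class `"growth_series"` with columns
#'   `time_h`, `biomass_gL`.
#' @export
growth_series <- function(time, biomass, noise_sd = NULL) {
  if (length(time) != length(biomass))
    abort_validation("time and biomass must have equal length")
  if (any(diff(time) <= 0)) abort_validation("time must be strictly increasing")
  if (any(time < 0)) abort_validation("time must be non-negative")
  if (any(biomass < 0)) abort_validation("biomass must be non-negative")
  out <- data.frame(time_h = as.numeric(time), biomass_gL = as.numeric(biomass))
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("growth_series", "data.frame")
  out
}

#' Linearize a logistic growth series
#'
#' Transforms biomass readings to `ln(x / (x_m - x))`, which is linear in
#' time with slope `mu_m` for an exact logistic curve. Rows with `x <= 0`
#' or `x >= x_m` fall outside the transform's domain and are dropped with
#' a warning reporting their count.
#'
#' @param series a [growth_series()].
#' @param x_m maximum attainable biomass (taken from the observed plateau
#'   in practice), must exceed every usable reading.
#' @return A `data.frame` with columns `time_h`, `z`; attribute
#'   `"n_dropped"` records excluded rows.
#' @export
linearize_growth <- function(series, x_m) {
  stopifnot(inherits(series, "growth_series"))
  check_number(x_m, "x_m", lower = 0, strict_lower = TRUE)
  usable <- series$biomass_gL > 0 & series$biomass_gL < x_m
  n_drop <- sum(!usable)
  if (n_drop > 0)
    warning(sprintf("dropping %d row(s) with biomass outside (0, x_m)", n_drop))
  if (sum(usable) < 2L)
    abort_validation("fewer than 2 usable rows after applying the transform domain")
  x <- series$biomass_gL[usable]
  out <- data.frame(time_h = series$time_h[usable], z = log(x / (x_m - x)))
  attr(out, "n_dropped") <- n_drop
  out
}

#' Fit logistic growth by linearized least squares
#'
#' Ordinary least squares on the linearization `ln(x/(x_m - x)) ~ t`.
#' The slope is the maximum specific growth rate `mu_m`; the intercept
#' identity `intercept = ln(x0/(x_m - x0))` yields the implied initial
#' biomass `x0 = x_m / (1 + exp(-intercept))`.
#'
#' @param series a [growth_series()].
#' @param x_m fixed maximum attainable biomass; defaults to 0.1% above
#'   the observed maximum (the empirical plateau).
#' @return An object of class `"growth_fit"` with components `mu_m`,
#'   `intercept`, `x0_implied`, `x_m`, residual sum of squares `rss`,
#'   the regression Jacobian (design matrix), and the underlying `lm` fit.
#' @examples
#' p <- growth_params(0.816, 1.543, 0.1934)
#' s <- gen_growth_curve(p, times = seq(0, 50, 2), noise_sd = 0)
#' fit_growth_linear(s, x_m = 1.543)
#' @export
fit_growth_linear <- function(series, x_m = NULL) {
  stopifnot(inherits(series, "growth_series"))
  if (is.null(x_m)) x_m <- max(series$biomass_gL) * 1.001
  lin <- linearize_growth(series, x_m)
  if (length(unique(lin$time_h)) < 2L)
    abort_validation("degenerate time column")
  fit <- stats::lm(z ~ time_h, data = lin)
  cf <- unname(stats::coef(fit))
  structure(list(mu_m = cf[2], intercept = cf[1],
                 x0_implied = x_m / (1 + exp(-cf[1])), x_m = x_m,
                 rss = sum(stats::residuals(fit)^2),
                 jacobian = stats::model.matrix(fit),
                 n_dropped = attr(lin, "n_dropped"),
                 lm_fit = fit, series = series),
            class = "growth_fit")
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(mu_m = object$mu_m, intercept = object$intercept,
    x0_implied = object$x0_implied)
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("Linearized logistic growth fit (x_m fixed at",
      format(x$x_m, digits = digits), "g/L)\n")
  cat("  mu_m      =", format(x$mu_m, digits = digits), "1/h\n")
  cat("  intercept =", format(x$intercept, digits = digits), "\n")
  cat("  implied x0 =", format(x$x0_implied, digits = digits), "g/L\n")
  if (x$n_dropped > 0) cat("  (", x$n_dropped, "rows outside transform domain )\n")
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  s <- summary(object$lm_fit)
  out <- list(coefficients = s$coefficients, mu_m = object$mu_m,
              x0_implied = object$x0_implied, x_m = object$x_m,
              rss = object$rss, r_squared = s$r.squared)
  class(out) <- "summary.growth_fit"
  out
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  cat("Linearized logistic growth fit\n")
  print(x$coefficients)
  cat("x_m =", x$x_m, "; implied x0 =", format(x$x0_implied),
      "; RSS =", format(x$rss), "; R^2 =", format(x$r_squared), "\n")
  invisible(x)
}

#' @export
predict.growth_fit <- function(object, newtime = NULL, ...) {
  if (is.null(newtime)) newtime <- object$series$time_h
  p <- growth_params(object$x0_implied, object$x_m, object$mu_m)
  logistic_growth(p, newtime)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  object$series$biomass_gL - predict(object)
}

#' @export
plot.growth_fit <- function(x, ...) {
  graphics::plot(x$series$time_h, x$series$biomass_gL,
                 xlab = "time (h)", ylab = "biomass (g/L DCW)",
                 main = "Logistic growth fit", ...)
  tt <- seq(min(x$series$time_h), max(x$series$time_h), length.out = 200)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Bayesian logistic growth fit with error-variance chain
#'
#' Samples the Gaussian-noise posterior over `(mu_m, x0)` (optionally also
#' `x_m`) with the DRAM sampler, co-sampling the error variance so that
#' the square root of the s2chain is the chain of the error standard
#' deviation. Priors are flat within the positivity bounds
#' `0 < x0 < x_m`, `mu_m > 0`. Returns the chain together with posterior
#' predictive envelopes over the observation times at the 50/90/95/99%
#' levels.
#'
#' @param series a [growth_series()].
#' @param x_m fixed carrying capacity; default the observed plateau.
#' @param x_m_free if `TRUE`, `x_m` is sampled as a third parameter.
#' @param n_steps chain length (default 5000).
#' @param levels envelope levels.
#' @param options a [dram_options()] list.
#' @param seed optional integer seed.
#' @return An object of class `"growth_bayes"`: `chain` (a
#'   `"dram_chain"` with s2chain), `envelope` (mean response),
#'   `envelope_obs` (observation level, Gaussian noise added),
#'   `sigma_draws`, and the posterior-mean [growth_params()].
#' @export
fit_growth_bayes <- function(series, x_m = NULL, x_m_free = FALSE,
                             n_steps = 5000,
                             levels = c(0.50, 0.90, 0.95, 0.99),
                             options = dram_options(), seed = NULL) {
  stopifnot(inherits(series, "growth_series"))
  if (is.null(x_m)) x_m <- max(series$biomass_gL) * 1.001
  start <- fit_growth_linear(series, x_m)
  tt <- series$time_h
  obs <- series$biomass_gL
  curve_at <- function(th, t) {
    xm <- if (x_m_free) th[3] else x_m
    xm / (1 + (xm - th[2]) / th[2] * exp(-th[1] * t))
  }
  valid <- function(th) {
    xm <- if (x_m_free) th[3] else x_m
    th[1] > 0 && th[2] > 0 && th[2] < xm && xm > 0
  }
  ss_fn <- function(th) {
    if (!valid(th)) return(Inf)
    sum((obs - curve_at(th, tt))^2)
  }
  log_post <- function(th, sigma2) {
    if (!valid(th)) return(-Inf)
    -0.5 * ss_fn(th) / sigma2 - 0.5 * length(obs) * log(sigma2)
  }
  init <- c(mu_m = start$mu_m, x0 = start$x0_implied)
  scale0 <- c(0.01^2, 0.01^2)
  if (x_m_free) { init <- c(init, x_m = x_m); scale0 <- c(scale0, (0.05 * x_m)^2) }
  opts <- options
  if (is.null(opts$init_cov)) opts$init_cov <- diag(scale0)
  chain <- run_dram(log_post, init, n_steps = n_steps, options = opts,
                    seed = seed, ss_fn = ss_fn, n_obs = length(obs),
                    param_names = names(init))
  env_seed <- if (is.null(seed)) NULL else seed + 1
  env <- predictive_envelope(chain, curve_at, grid = tt, levels = levels,
                             seed = env_seed)
  env_obs <- predictive_envelope(chain, curve_at, grid = tt, levels = levels,
                                 noise = "gaussian", seed = env_seed)
  post <- colMeans(chain_draws(chain))
  est <- growth_params(post[["x0"]],
                       if (x_m_free) post[["x_m"]] else x_m,
                       post[["mu_m"]])
  structure(list(chain = chain, envelope = env, envelope_obs = env_obs,
                 sigma_draws = sqrt(chain_s2(chain)),
                 estimate = est, x_m_free = x_m_free, series = series),
            class = "growth_bayes")
}

#' @export
print.growth_bayes <- function(x, digits = 4, ...) {
  cat("Bayesian logistic growth fit (DRAM, ", x$chain$n_steps,
      " steps)\n", sep = "")
  cat("posterior means: mu_m =", format(x$estimate$mu_m, digits = digits),
      "1/h, x0 =", format(x$estimate$x0, digits = digits),
      "g/L, x_m =", format(x$estimate$x_m, digits = digits), "g/L\n")
  cat("posterior mean error sd:", format(mean(x$sigma_draws), digits = digits),
      "g/L\n")
  invisible(x)
}

#' @export
summary.growth_bayes <- function(object, ...) chain_diagnostics(object$chain)
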