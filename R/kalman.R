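#' pH time series
#'
#' @param time hours, strictly increasing (2-h sampling in the default
#'   serum-bottle protocol).
#' @param observed_pH measured pH per time point, in (0, 14).
#' @param latent_pH optional noise-free latent pH (synthetic data only).
#' @return A `data.frame` of class `"ph_series"` with columns `time_h`,
#'   `pH` and optionally `latent_pH`.
#' @export
ph_series <- function(time, observed_pH, latent_pH = NULL) {
  if (length(time) != length(observed_pH))
    abort_validation("time and observed_pH must have equal length")
  if (any(diff(time) <= 0)) abort_validation("time must be strictly increasing")
  if (any(observed_pH <= 0 | observed_pH >= 14))
    abort_validation("pH must lie in (0, 14)")
  out <- data.frame(time_h = as.numeric(time), pH = as.numeric(observed_pH))
  if (!is.null(latent_pH)) {
    if (length(latent_pH) != length(time))
      abort_validation("latent_pH length must match time")
    out$latent_pH <- as.numeric(latent_pH)
  }
  class(out) <- c("ph_series", "data.frame")
  out
}

#' Kalman filter configuration
#'
#' Hyperparameters of the one-dimensional linear-Gaussian state model:
#' per-step process-noise variance `Q`, measurement-noise variance `R`,
#' and the initial state distribution. When left `NULL`, `Q` and `R`
#' default to half the lag-1 difference variance of the observed series
#' each, and the state is initialized at the first observation.
#'
#' @param process_var `Q >= 0`.
#' @param meas_var `R >= 0` (`R = 0` is handled as the exact-measurement
#'   limit, gain 1).
#' @param init_mean initial state mean.
#' @param init_var initial state variance, `> 0`.
#' @param state `"random-walk"` (identity transition, default) or
#'   `"local-trend"` (level + slope state).
#' @return A list of class `"kalman_config"`.
#' @export
kalman_config <- function(process_var = NULL, meas_var = NULL,
                          init_mean = NULL, init_var = NULL,
                          state = c("random-walk", "local-trend")) {
  state <- match.arg(state)
  if (!is.null(process_var)) check_number(process_var, "process_var", lower = 0)
  if (!is.null(meas_var)) check_number(meas_var, "meas_var", lower = 0)
  if (!is.null(init_var)) check_number(init_var, "init_var", lower = 0,
                                       strict_lower = TRUE)
  structure(list(process_var = process_var, meas_var = meas_var,
                 init_mean = init_mean, init_var = init_var, state = state),
            class = "kalman_config")
}

#' One-dimensional Kalman filter for pH trajectories
#'
#' Exact minimum-mean-squared-error filtering of a pH series under a
#' random-walk (or, optionally, local linear trend) state with Gaussian
#' process and measurement noise: predict leaves the mean unchanged and
#' inflates the variance by `Q`; update applies the gain
#' `K = P / (P + R)`.
#'
#' @param series a [ph_series()] (or any data frame with `time_h` and
#'   `pH` columns).
#' @param config a [kalman_config()]; `NULL` uses the data-driven
#'   defaults.
#' @return An object of class `"kalman_fit"`: a data frame `states` with
#'   per-step `filtered_mean`, `filtered_var`, `gain` and `innovation`,
#'   plus the resolved `config`.
#' @examples
#' s <- gen_ph_trajectory("pH5.0", seed = 1)
#' kf <- kalman_filter(s)
#' tail(kf$states$filtered_mean, 1)
#' @export
kalman_filter <- function(series, config = NULL) {
  if (!inherits(series, "ph_series"))
    series <- ph_series(series$time_h, series$pH, series$latent_pH)
  obs <- series$pH
  n <- length(obs)
  if (n < 2L) abort_validation("need at least 2 observations")
  if (is.null(config)) config <- kalman_config()
  v <- stats::var(diff(obs))
  Q <- if (is.null(config$process_var)) v / 2 else config$process_var
  R <- if (is.null(config$meas_var)) v / 2 else config$meas_var
  m0 <- if (is.null(config$init_mean)) obs[1] else config$init_mean
  P0 <- if (is.null(config$init_var)) max(v, 1e-12) else config$init_var

  if (config$state == "local-trend") {
    res <- kalman_local_trend(series$time_h, obs, Q, R, m0, P0)
  } else {
    m <- numeric(n); P <- numeric(n); K <- numeric(n); innov <- numeric(n)
    mp <- m0; Pp <- P0
    for (i in seq_len(n)) {
      if (i > 1) Pp <- Pp + Q              # predict: mean unchanged
      k <- if (Pp + R > 0) Pp / (Pp + R) else 1  # R = 0, Pp = 0: exact repeat
      innov[i] <- obs[i] - mp
      mp <- mp + k * innov[i]
      Pp <- (1 - k) * Pp
      m[i] <- mp; P[i] <- Pp; K[i] <- k
    }
    res <- data.frame(time_h = series$time_h, observed = obs,
                      filtered_mean = m, filtered_var = P,
                      gain = K, innovation = innov)
  }
  structure(list(states = res,
                 config = kalman_config(Q, R, m0, max(P0, 1e-12),
                                        state = config$state),
                 series = series),
            class = "kalman_fit")
}

# level + slope state with identity-ish transition; slope receives the
# process noise. Gain reported for the level component.
kalman_local_trend <- function(time, obs, Q, R, m0, P0) {
  n <- length(obs)
  m <- c(m0, 0); P <- diag(c(P0, P0))
  H <- matrix(c(1, 0), 1, 2)
  out_m <- numeric(n); out_P <- numeric(n); out_K <- numeric(n)
  innov <- numeric(n)
  for (i in seq_len(n)) {
    if (i > 1) {
      dt <- time[i] - time[i - 1]
      F <- matrix(c(1, 0, dt, 1), 2, 2)
      m <- drop(F %*% m)
      P <- F %*% P %*% t(F) + diag(c(0, Q))
    }
    S <- drop(H %*% P %*% t(H)) + R
    K <- if (S > 0) drop(P %*% t(H)) / S else c(1, 0)
    innov[i] <- obs[i] - m[1]
    m <- m + K * innov[i]
    P <- (diag(2) - K %*% H) %*% P
    out_m[i] <- m[1]; out_P[i] <- P[1, 1]; out_K[i] <- K[1]
  }
  data.frame(time_h = time, observed = obs, filtered_mean = out_m,
             filtered_var = out_P, gain = out_K, innovation = innov)
}

#' @export
print.kalman_fit <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat("Kalman filter (", cfg$state, " state), ", nrow(x$states),
      " steps\n", sep = "")
  cat("Q =", format(cfg$process_var, digits = digits),
      " R =", format(cfg$meas_var, digits = digits), "\n")
  cat("terminal filtered mean:",
      format(tail_value(x$states$filtered_mean), digits = digits), "\n")
  invisible(x)
}

tail_value <- function(v) v[length(v)]

#' @export
fitted.kalman_fit <- function(object, ...) object$states$filtered_mean

#' @export
residuals.kalman_fit <- function(object, ...) object$states$innovation

#' @export
plot.kalman_fit <- function(x, ...) {
  s <- x$states
  graphics::plot(s$time_h, s$observed, xlab = "time (h)", ylab = "pH",
                 main = "Kalman-filtered pH trajectory", ...)
  graphics::lines(s$time_h, s$filtered_mean)
  invisible(x)
}

#' Measurement versus filter error
#'
#' Mean squared error of the raw observations and of the filtered means
#' against a known latent trajectory (synthetic runs); the filter, being
#' the MMSE estimator for the linear-Gaussian model, beats the raw
#' measurements on average when correctly specified.
#'
#' @param result a [kalman_filter()] fit.
#' @param truth latent pH values, same length as the filtered series.
#' @return A list with `measurement_mse` and `filter_mse`.
#' @export
error_comparison <- function(result, truth) {
  stopifnot(inherits(result, "kalman_fit"))
  s <- result$states
  if (length(truth) != nrow(s))
    abort_validation("truth length must match the filtered series")
  list(measurement_mse = mean((s$observed - truth)^2),
       filter_mse = mean((s$filtered_mean - truth)^2))
}

#' Steady-state filtered variance
#'
#' Closed-form fixed point `P*` of the constant-parameter scalar
#' random-walk filter, solving `P* = (P* + Q) R / (P* + Q + R)`, i.e.
#' the positive root of `P*^2 + Q P* - Q R = 0`.
#'
#' @param Q process variance, `>= 0`.
#' @param R measurement variance, `>= 0`.
#' @return The steady-state updated variance.
#' @export
kalman_steady_state <- function(Q, R) {
  check_number(Q, "Q", lower = 0)
  check_number(R, "R", lower = 0)
  (-Q + sqrt(Q^2 + 4 * Q * R)) / 2
}
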