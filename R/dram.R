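#' DRAM sampler options
#'
#' Tuning constants for [run_dram()]. Defaults follow common DRAM
#' practice: proposal scale `2.38^2 / d` times an initial covariance,
#' covariance adaptation from the chain history every `adapt_interval`
#' steps, and one delayed-rejection fallback stage at a down-scaled
#' proposal after a first rejection.
#'
#' @param init_cov initial proposal covariance (matrix or scalar for a
#'   multiple of the identity); scaled internally by `2.38^2 / d`.
#' @param adapt_interval steps between proposal-covariance adaptations.
#' @param dr_scale standard-deviation down-scaling of the delayed-rejection
#'   stage proposal (default 1/5).
#' @param burn_frac fraction of initial draws discarded by summaries and
#'   envelopes (default 0.2).
#' @param adapt_eps small diagonal regularization added during adaptation.
#' @return A list of class `"dram_options"`.
#' @export
dram_options <- function(init_cov = NULL, adapt_interval = 100,
                         dr_scale = 0.2, burn_frac = 0.2,
                         adapt_eps = 1e-10) {
  check_number(adapt_interval, "adapt_interval", lower = 2)
  check_number(dr_scale, "dr_scale", lower = 0, strict_lower = TRUE, upper = 1)
  check_number(burn_frac, "burn_frac", lower = 0, upper = 0.9)
  structure(list(init_cov = init_cov, adapt_interval = adapt_interval,
                 dr_scale = dr_scale, burn_frac = burn_frac,
                 adapt_eps = adapt_eps),
            class = "dram_options")
}

mvn_draw <- function(mean, chol_cov) {
  drop(mean + t(chol_cov) %*% stats::rnorm(length(mean)))
}

# log of a symmetric Gaussian transition density up to a constant,
# with covariance given through its upper-triangular Cholesky factor
log_q <- function(from, to, chol_cov) {
  z <- backsolve(chol_cov, to - from, transpose = TRUE)
  -0.5 * sum(z^2)
}

#' Delayed-rejection adaptive-Metropolis sampler
#'
#' Random-walk Metropolis sampling with two standard accelerations: after
#' a first rejection a second, down-scaled proposal is tried with the
#' delayed-rejection acceptance correction, and the proposal covariance is
#' periodically re-estimated from the chain history (adaptive Metropolis).
#' For Gaussian-noise regression models a conjugate error-variance chain
#' (`s2chain`) can be co-sampled by supplying `ss_fn`; each step then
#' draws `sigma^2` from its inverse-gamma full conditional given the
#' current parameter's residual sum of squares.
#'
#' @param log_posterior function of the parameter vector returning the log
#'   posterior density (up to a constant); when `ss_fn` is supplied it is
#'   called as `log_posterior(theta, sigma2)`. Must be finite at `init`;
#'   `-Inf` is treated as rejection, `NaN` aborts.
#' @param init numeric starting parameter vector.
#' @param n_steps chain length (default 5000, minimum 100).
#' @param options a [dram_options()] list.
#' @param seed optional integer seed; fixed seed gives bit-identical draws.
#' @param ss_fn optional function of `theta` returning the residual sum of
#'   squares of a Gaussian model; enables the s2chain.
#' @param n_obs number of Gaussian observations behind `ss_fn`.
#' @param s2_prior inverse-gamma prior `c(shape, rate)` on `sigma^2`
#'   (default vague `c(0.01, 0.01)`).
#' @param param_names optional column names for the draws.
#' @return An object of class `"dram_chain"`: `draws` (`n_steps x npar`
#'   matrix), optional `s2chain`, `acceptance_rate`, `n_steps`, `seed`,
#'   and the burn-in fraction used by summaries.
#' @examples
#' ch <- run_dram(function(th) -0.5 * th^2, init = 0, n_steps = 500, seed = 1)
#' summary(ch)
#' @export
run_dram <- function(log_posterior, init, n_steps = 5000,
                     options = dram_options(), seed = NULL,
                     ss_fn = NULL, n_obs = NULL,
                     s2_prior = c(shape = 0.01, rate = 0.01),
                     param_names = NULL) {
  check_number(n_steps, "n_steps", lower = 100)
  d <- length(init)
  sd_scale <- 2.38^2 / d
  C0 <- options$init_cov
  if (is.null(C0)) C0 <- diag(d)
  if (is.matrix(C0)) stopifnot(nrow(C0) == d) else C0 <- diag(C0, d)
  use_s2 <- !is.null(ss_fn)
  if (use_s2) stopifnot(is.numeric(n_obs), n_obs >= 1)

  with_seed(seed, {
    sigma2 <- if (use_s2) sample_error_variance(ss_fn(init), n_obs, s2_prior) else NULL
    lp <- function(th) {
      v <- if (use_s2) log_posterior(th, sigma2) else log_posterior(th)
      if (is.nan(v)) stop("log_posterior returned NaN at theta = ",
                          paste(signif(th, 4), collapse = ", "))
      v
    }
    cur <- as.numeric(init)
    cur_lp <- lp(cur)
    if (!is.finite(cur_lp))
      abort_validation("log_posterior must be finite at init")

    R1 <- chol(sd_scale * C0)
    draws <- matrix(NA_real_, n_steps, d)
    s2chain <- if (use_s2) numeric(n_steps) else NULL
    draws[1L, ] <- cur
    if (use_s2) s2chain[1L] <- sigma2
    n_acc <- 0L
    run_mean <- cur
    run_cov <- matrix(0, d, d)

    for (i in 2:n_steps) {
      if (use_s2) {
        sigma2 <- sample_error_variance(ss_fn(cur), n_obs, s2_prior)
        cur_lp <- lp(cur)        # posterior depends on the fresh sigma2
      }
      y1 <- mvn_draw(cur, R1)
      lp1 <- lp(y1)
      a1 <- min(1, exp(lp1 - cur_lp))
      if (is.finite(lp1) && stats::runif(1) < a1) {
        cur <- y1; cur_lp <- lp1; n_acc <- n_acc + 1L
      } else {
        # delayed-rejection stage: narrower proposal, corrected acceptance
        R2 <- options$dr_scale * R1
        y2 <- mvn_draw(cur, R2)
        lp2 <- lp(y2)
        if (is.finite(lp2)) {
          a1_rev <- min(1, exp(lp1 - lp2))   # alpha1(y2 -> y1)
          num <- lp2 + log_q(y2, y1, R1) + log1p(-a1_rev)
          den <- cur_lp + log_q(cur, y1, R1) + log1p(-a1)
          # a1_rev = 1 makes the DR numerator vanish: certain rejection
          if (a1_rev < 1 && a1 < 1 && stats::runif(1) < exp(num - den)) {
            cur <- y2; cur_lp <- lp2; n_acc <- n_acc + 1L
          }
        }
      }
      draws[i, ] <- cur
      if (use_s2) s2chain[i] <- sigma2

      # recursive chain mean/covariance for adaptation
      delta <- cur - run_mean
      run_mean <- run_mean + delta / i
      run_cov <- run_cov * (i - 2) / (i - 1) + tcrossprod(delta) / i
      if (i %% options$adapt_interval == 0 && i > d + 2) {
        Cad <- sd_scale * (run_cov + options$adapt_eps * diag(d))
        R_try <- tryCatch(chol(Cad), error = function(e) NULL)
        if (!is.null(R_try)) R1 <- R_try
      }
    }

    if (is.null(param_names))
      param_names <- paste0("par", seq_len(d))
    colnames(draws) <- param_names
    structure(list(draws = draws, s2chain = s2chain,
                   acceptance_rate = n_acc / (n_steps - 1),
                   n_steps = n_steps, seed = seed,
                   burn_frac = options$burn_frac),
              class = "dram_chain")
  })
}

#' Conjugate error-variance draw
#'
#' One inverse-gamma draw of the Gaussian error variance `sigma^2` given a
#' residual sum of squares, as used per DRAM step for Gaussian-noise
#' models (the square root of the resulting s2chain is the chain of the
#' error standard deviation).
#'
#' @param residual_ss residual sum of squares, `>= 0`.
#' @param n_obs number of observations, `>= 1`.
#' @param prior inverse-gamma prior `c(shape, rate)`.
#' @return A single positive draw of `sigma^2`.
#' @export
sample_error_variance <- function(residual_ss, n_obs,
                                  prior = c(shape = 0.01, rate = 0.01)) {
  if (!is.numeric(residual_ss) || residual_ss < 0)
    abort_validation("residual_ss must be non-negative")
  check_number(n_obs, "n_obs", lower = 1)
  1 / stats::rgamma(1, shape = prior[[1]] + n_obs / 2,
                    rate = prior[[2]] + residual_ss / 2)
}

# extract post-burn-in draw matrix from a dram_chain or plain matrix
chain_draws <- function(chain, burn = NULL) {
  if (inherits(chain, "dram_chain")) {
    if (is.null(burn)) burn <- chain$burn_frac
    m <- chain$draws
  } else {
    if (is.null(burn)) burn <- 0
    m <- as.matrix(chain)
  }
  if (nrow(m) == 0L) abort_validation("chain is empty")
  drop_n <- floor(burn * nrow(m))
  m[(drop_n + 1):nrow(m), , drop = FALSE]
}

chain_s2 <- function(chain, burn = NULL) {
  if (!inherits(chain, "dram_chain") || is.null(chain$s2chain)) return(NULL)
  if (is.null(burn)) burn <- chain$burn_frac
  s2 <- chain$s2chain
  s2[(floor(burn * length(s2)) + 1):length(s2)]
}

#' Posterior predictive envelope over a predictor grid
#'
#' Evaluates a model function on a random subset of post-burn-in draws
#' over a predictor grid and returns central quantile bands at the
#' requested probability levels (defaults 50/90/95/99%). Observation-level
#' envelopes are obtained by supplying `noise`, which adds one noise
#' realization per draw and grid point: `"gaussian"` uses the chain's
#' s2chain, or pass a function `noise(mu, draw)` returning observations
#' (e.g. binomial sampling).
#'
#' @param chain a [run_dram()] result (or plain draw matrix).
#' @param model_fn function `model_fn(theta, grid)` returning the model
#'   mean response on the grid.
#' @param grid ordered predictor values.
#' @param levels central-probability levels, all in (0, 1).
#' @param n_sub number of draws in the random subset (default 500).
#' @param noise `NULL` for a mean-response envelope, `"gaussian"`, or a
#'   function `noise(mu, theta)`.
#' @param seed optional integer seed.
#' @param burn optional burn-in override.
#' @return An object of class `"envelope_band"`: `grid`, `levels`, and
#'   `lower`/`upper` matrices (one row per level). Bands are nested by
#'   construction of the central quantiles.
#' @export
predictive_envelope <- function(chain, model_fn, grid,
                                levels = c(0.50, 0.90, 0.95, 0.99),
                                n_sub = 500, noise = NULL, seed = NULL,
                                burn = NULL) {
  if (any(levels <= 0 | levels >= 1)) abort_validation("levels must lie in (0,1)")
  draws <- chain_draws(chain, burn)
  s2 <- chain_s2(chain, burn)
  gaussian_noise <- identical(noise, "gaussian")
  if (gaussian_noise && is.null(s2))
    abort_validation("noise = 'gaussian' needs a chain with an s2chain")
  with_seed(seed, {
    idx <- if (nrow(draws) == n_sub) seq_len(nrow(draws))
           else sample.int(nrow(draws), n_sub, replace = nrow(draws) < n_sub)
    sims <- matrix(NA_real_, length(idx), length(grid))
    for (j in seq_along(idx)) {
      th <- draws[idx[j], ]
      mu <- model_fn(th, grid)
      if (gaussian_noise) mu <- mu + stats::rnorm(length(grid), 0, sqrt(s2[idx[j]]))
      else if (is.function(noise)) mu <- noise(mu, th)
      sims[j, ] <- mu
    }
    levels <- sort(levels)
    qs <- function(p) apply(sims, 2, stats::quantile, probs = p, names = FALSE)
    lower <- t(vapply(levels, function(l) qs((1 - l) / 2), numeric(length(grid))))
    upper <- t(vapply(levels, function(l) qs(1 - (1 - l) / 2), numeric(length(grid))))
    rownames(lower) <- rownames(upper) <- paste0(100 * levels, "%")
    structure(list(grid = grid, levels = levels, lower = lower, upper = upper,
                   median = qs(0.5)),
              class = "envelope_band")
  })
}

#' @export
print.envelope_band <- function(x, ...) {
  cat("Predictive envelope over", length(x$grid), "grid points; levels:",
      paste0(100 * x$levels, "%", collapse = ", "), "\n")
  invisible(x)
}

#' Chain summary diagnostics
#'
#' Per-parameter posterior mean, standard deviation and central interval
#' from the post-burn-in draws, plus the acceptance rate and, when
#' present, the same summaries for the error standard deviation
#' `sqrt(s2chain)`.
#'
#' @param chain a [run_dram()] result.
#' @param level central-interval probability (default 0.95).
#' @param burn optional burn-in override.
#' @return A list of class `"dram_diagnostics"` with a `summary` matrix.
#' @export
chain_diagnostics <- function(chain, level = 0.95, burn = NULL) {
  draws <- chain_draws(chain, burn)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  smry <- t(apply(draws, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      stats::quantile(v, probs, names = FALSE))))
  colnames(smry) <- c("mean", "sd", paste0(100 * probs, "%"))
  s2 <- chain_s2(chain, burn)
  sigma <- if (!is.null(s2))
    c(mean = mean(sqrt(s2)), sd = stats::sd(sqrt(s2)),
      stats::quantile(sqrt(s2), probs, names = FALSE)) else NULL
  structure(list(summary = smry, sigma = sigma,
                 acceptance_rate = if (inherits(chain, "dram_chain"))
                   chain$acceptance_rate else NA_real_,
                 n_draws = nrow(draws)),
            class = "dram_diagnostics")
}

#' @export
print.dram_diagnostics <- function(x, digits = 4, ...) {
  cat("DRAM chain diagnostics (", x$n_draws, " retained draws, acceptance ",
      format(x$acceptance_rate, digits = 3), ")\n", sep = "")
  print(round(x$summary, digits))
  if (!is.null(x$sigma)) {
    cat("error sd (sqrt s2chain):\n")
    print(round(x$sigma, digits))
  }
  invisible(x)
}

#' @export
print.dram_chain <- function(x, ...) {
  cat("DRAM chain:", x$n_steps, "steps x", ncol(x$draws), "parameter(s);",
      "acceptance rate", format(x$acceptance_rate, digits = 3), "\n")
  if (!is.null(x$s2chain)) cat("includes error-variance chain (s2chain)\n")
  invisible(x)
}

#' @export
summary.dram_chain <- function(object, level = 0.95, ...) {
  chain_diagnostics(object, level = level)
}

#' @export
as.matrix.dram_chain <- function(x, ...) x$draws

#' Repeat a seeded chain run and pool summaries
#'
#' Re-runs a chain-producing function under distinct derived seeds and
#' collects the per-run posterior means, supporting stability checks of
#' the kind done by repeating sampler runs many times.
#'
#' @param run_fn function of a single integer seed returning a
#'   `"dram_chain"`.
#' @param n_repeats number of repeated runs (default 500).
#' @param seed base seed from which run seeds are derived.
#' @return A matrix of per-run posterior means (one row per run).
#' @export
repeat_runs <- function(run_fn, n_repeats = 500, seed = 1) {
  check_number(n_repeats, "n_repeats", lower = 1)
  seeds <- seed + seq_len(n_repeats) - 1
  out <- lapply(seeds, function(s) colMeans(chain_draws(run_fn(s))))
  do.call(rbind, out)
}

#' Write a chain to CSV
#'
#' One row per draw; the error-variance chain, when present, is appended
#' as a final `s2` column.
#'
#' @param chain a `"dram_chain"`.
#' @param path output file path.
#' @export
write_chain_csv <- function(chain, path) {
  stopifnot(inherits(chain, "dram_chain"))
  df <- as.data.frame(chain$draws)
  if (!is.null(chain$s2chain)) df$s2 <- chain$s2chain
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an envelope to CSV
#'
#' Long format: one row per (grid point, level) with lower and upper
#' bounds.
#'
#' @param env an `"envelope_band"`.
#' @param path output file path.
#' @export
write_envelope_csv <- function(env, path) {
  stopifnot(inherits(env, "envelope_band"))
  df <- do.call(rbind, lapply(seq_along(env$levels), function(i)
    data.frame(grid = env$grid, level = env$levels[i],
               lower = env$lower[i, ], upper = env$upper[i, ])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
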