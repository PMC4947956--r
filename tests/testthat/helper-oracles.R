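# Independent oracles used across test files. These deliberately avoid
# the package's own solution paths: brute-force grids, direct arithmetic
# and a hand-rolled ODE integrator.

# Two-stage fine-grid maximizer of the binomial log-likelihood over
# (beta0, beta1). Evaluates the likelihood by direct arithmetic.
grid_mle_oracle <- function(table, link = "logit",
                            b0_range = c(-30, 0), b1_range = c(0, 20)) {
  ll_direct <- function(b0, b1) {
    eta <- b0 + b1 * log10(table$dose)
    p <- switch(link, logit = 1 / (1 + exp(-eta)), probit = pnorm(eta),
                cloglog = 1 - exp(-exp(eta)))
    y <- table$deaths; m <- table$n - y
    sum(lchoose(table$n, y) + ifelse(y > 0, y * log(p), 0) +
          ifelse(m > 0, m * log(1 - p), 0))
  }
  best <- c(mean(b0_range), mean(b1_range))
  span <- c(diff(b0_range), diff(b1_range)) / 2
  # gentle zoom: the likelihood ridge in (beta0, beta1) is strongly
  # diagonal, so aggressive axis-aligned shrinking can strand the grid
  for (stage in 1:14) {
    b0s <- seq(best[1] - span[1], best[1] + span[1], length.out = 41)
    b1s <- seq(best[2] - span[2], best[2] + span[2], length.out = 41)
    vals <- outer(b0s, b1s, Vectorize(ll_direct))
    idx <- arrayInd(which.max(vals), dim(vals))
    best <- c(b0s[idx[1]], b1s[idx[2]])
    span <- span * 0.45
  }
  best
}

# Classical fourth-order Runge-Kutta integration of dx/dt = f(x)
rk4_integrate <- function(f, x0, times) {
  x <- numeric(length(times))
  x[1] <- x0
  for (i in 2:length(times)) {
    h <- times[i] - times[i - 1]
    k1 <- f(x[i - 1])
    k2 <- f(x[i - 1] + h / 2 * k1)
    k3 <- f(x[i - 1] + h / 2 * k2)
    k4 <- f(x[i - 1] + h * k3)
    x[i] <- x[i - 1] + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  x
}

# Batch Gaussian-Bayes posterior mean of a constant state after
# observing y_1..y_n with noise variance R, starting from N(m0, P0)
batch_mean_oracle <- function(y, R, m0, P0) {
  (m0 / P0 + cumsum(y) / R) / (1 / P0 + seq_along(y) / R)
}
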