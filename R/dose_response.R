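#' Construct a dose-response table
#'
#' Assembles and validates a per-dose irradiation outcome table: at each
#' absorbed dose (Gy) a known number of cells was irradiated and the number
#' killed recorded. Lethality is modelled as binomial with a dose-dependent
#' success probability, with base-10 log dose as the covariate.
#'
#' @param dose absorbed doses in Gy, strictly positive and unique.
#' @param n number of cells irradiated per dose, non-negative integers.
#' @param deaths number of cells killed per dose, `0 <= deaths <= n`.
#' @return A `data.frame` of class `"dose_table"` with columns `dose`,
#'   `log_dose` (`log10(dose)`), `n` and `deaths`.
#' @examples
#' dose_table(dose = c(15, 90), n = c(5000, 7000), deaths = c(600, 7000))
#' @export
dose_table <- function(dose, n, deaths) {
  if (length(dose) != length(n) || length(n) != length(deaths))
    abort_validation("dose, n and deaths must have equal length")
  if (any(!is.finite(dose)) || any(dose <= 0))
    abort_validation("all doses must be positive (log-dose undefined otherwise)")
  if (anyDuplicated(dose))
    abort_validation("doses must be unique")
  if (any(n < 0) || any(deaths < 0) || any(deaths > n))
    abort_validation("deaths must satisfy 0 <= deaths <= n in every row")
  out <- data.frame(dose = as.numeric(dose), log_dose = log10(dose),
                    n = as.numeric(n), deaths = as.numeric(deaths))
  class(out) <- c("dose_table", "data.frame")
  out
}

#' Packaged irradiation lethality table
#'
#' Loads the packaged 16-point heavy-ion irradiation outcome table
#' (doses 15-90 Gy, cell totals and deaths per dose) shipped as a
#' plain-text fixture. The log-dose column is always recomputed as
#' `log10(dose)`.
#'
#' @return A [dose_table()] with 16 rows.
#' @export
table1_dose_response <- function() {
  path <- system.file("extdata", "table1_dose_response.csv",
                      package = "ionferm", mustWork = TRUE)
  read_input_table(path, kind = "dose")
}

#' Dose-response link parameters
#'
#' @param beta0 intercept of the linear predictor.
#' @param beta1 slope per unit log10-dose.
#' @param link link function: `"logit"` (default), `"probit"` or `"cloglog"`.
#' @return A list of class `"link_params"`.
#' @export
link_params <- function(beta0, beta1, link = c("logit", "probit", "cloglog")) {
  link <- match.arg(link)
  check_number(beta0, "beta0")
  check_number(beta1, "beta1")
  structure(list(beta0 = beta0, beta1 = beta1, link = link),
            class = "link_params")
}

inv_link <- function(eta, link) {
  switch(link,
         logit   = stats::plogis(eta),
         probit  = stats::pnorm(eta),
         cloglog = -expm1(-exp(eta)),
         abort_validation(sprintf("unknown link '%s'", link)))
}

#' Lethality probability at a given dose
#'
#' Evaluates the dose-response curve `p(dose)` obtained by applying the
#' inverse link to the linear predictor `beta0 + beta1 * log10(dose)`.
#'
#' @param params a [link_params()] object.
#' @param dose absorbed dose(s) in Gy, strictly positive.
#' @return Probabilities in `[0, 1]`, one per dose.
#' @examples
#' lethality_probability(link_params(0, 0), dose = 40)  # 0.5
#' @export
lethality_probability <- function(params, dose) {
  stopifnot(inherits(params, "link_params"))
  if (any(!is.finite(dose)) || any(dose <= 0))
    abort_validation("dose must be strictly positive")
  inv_link(params$beta0 + params$beta1 * log10(dose), params$link)
}

#' Binomial log-likelihood of a dose-response table
#'
#' Full binomial log-likelihood including the binomial coefficient term:
#' `sum_i [ log C(n_i, y_i) + y_i log p_i + (n_i - y_i) log(1 - p_i) ]`.
#' Boundary probabilities return `-Inf` (not an error) when they conflict
#' with the observed counts; rows with `n = 0` contribute nothing.
#'
#' @param params a [link_params()] object.
#' @param table a [dose_table()].
#' @return A single real value, possibly `-Inf`.
#' @export
dose_log_likelihood <- function(params, table) {
  stopifnot(inherits(table, "dose_table"))
  p <- lethality_probability(params, table$dose)
  y <- table$deaths
  m <- table$n - y
  term <- function(k, lp) ifelse(k > 0, k * lp, 0)  # 0 * log(0) := 0
  sum(lchoose(table$n, y) + term(y, log(p)) + term(m, log1p(-p)))
}

#' Deviance of a dose-response model
#'
#' Deviance diagnostic defined as `-2 * log(likelihood)`, the discrepancy
#' used by the posterior predictive check. A `-Inf` log-likelihood
#' propagates as `+Inf` deviance.
#'
#' @inheritParams dose_log_likelihood
#' @return A single non-negative-infinity-capable real value.
#' @export
dose_deviance <- function(params, table) {
  -2 * dose_log_likelihood(params, table)
}

#' Fit a binomial dose-response model by maximum likelihood
#'
#' Fits the generalized linear lethality model by iteratively reweighted
#' least squares. The covariate is base-10 log dose by default (matching
#' the tabulated log-dose column); raw dose is available behind
#' `covariate = "raw"`.
#'
#' @param table a [dose_table()].
#' @param link link function, see [link_params()].
#' @param covariate `"log10"` (default) or `"raw"` dose scale.
#' @return An object of class `"dose_fit"`: the fitted [link_params()],
#'   the observed-information covariance matrix, the full log-likelihood
#'   and deviance (binomial coefficient included), and the data.
#' @examples
#' fit <- fit_dose_response(table1_dose_response())
#' coef(fit)
#' @export
fit_dose_response <- function(table, link = c("logit", "probit", "cloglog"),
                              covariate = c("log10", "raw")) {
  stopifnot(inherits(table, "dose_table"))
  link <- match.arg(link)
  covariate <- match.arg(covariate)
  keep <- table$n > 0
  if (sum(keep) < 2L || length(unique(table$dose[keep])) < 2L)
    abort_validation("need at least 2 distinct doses with cells at risk")
  frac <- table$deaths[keep] / table$n[keep]
  if (all(frac == 0) || all(frac == 1))
    abort_validation("degenerate outcomes: all rows fully alive or fully dead")
  x <- if (covariate == "log10") table$log_dose[keep] else table$dose[keep]
  fit <- stats::glm(cbind(table$deaths[keep], table$n[keep] - table$deaths[keep]) ~ x,
                    family = stats::binomial(link = link))
  cf <- unname(stats::coef(fit))
  if (!fit$converged || any(abs(cf) > 1e4))
    stop(errorCondition(
      "IRLS failed to converge: likely complete separation of outcomes",
      class = c("ionferm_separation_error", "error")))
  params <- link_params(cf[1], cf[2], link)
  ll <- if (covariate == "log10") dose_log_likelihood(params, table) else {
    p <- inv_link(cf[1] + cf[2] * table$dose, link)
    k <- table$deaths; m <- table$n - k
    sum(lchoose(table$n, k) + ifelse(k > 0, k * log(p), 0) +
          ifelse(m > 0, m * log1p(-p), 0))
  }
  vc <- stats::vcov(fit)
  dimnames(vc) <- list(c("beta0", "beta1"), c("beta0", "beta1"))
  structure(list(params = params, vcov = vc, loglik = ll,
                 deviance = -2 * ll, covariate = covariate,
                 table = table, glm_fit = fit),
            class = "dose_fit")
}

#' @export
coef.dose_fit <- function(object, ...) {
  c(beta0 = object$params$beta0, beta1 = object$params$beta1)
}

#' @export
vcov.dose_fit <- function(object, ...) object$vcov

#' @export
logLik.dose_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, nobs = nrow(object$table), class = "logLik")
}

#' @export
print.dose_fit <- function(x, digits = 4, ...) {
  cat("Binomial dose-response fit (", x$params$link, " link, ",
      if (x$covariate == "log10") "log10-dose" else "raw-dose",
      " covariate)\n", sep = "")
  print(round(coef(x), digits))
  cat("log-likelihood:", format(x$loglik, digits = digits),
      "  deviance:", format(x$deviance, digits = digits), "\n")
  invisible(x)
}

#' @export
summary.dose_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  out <- list(coefficients = cbind(Estimate = coef(object), `Std. Error` = se),
              link = object$params$link, covariate = object$covariate,
              loglik = object$loglik, deviance = object$deviance,
              n_rows = nrow(object$table))
  class(out) <- "summary.dose_fit"
  out
}

#' @export
print.summary.dose_fit <- function(x, ...) {
  cat("Binomial dose-response model,", x$link, "link on",
      if (x$covariate == "log10") "log10(dose)" else "dose", "\n")
  print(x$coefficients)
  cat(x$n_rows, "dose groups; log-likelihood", format(x$loglik),
      "; deviance", format(x$deviance), "\n")
  invisible(x)
}

#' @export
predict.dose_fit <- function(object, newdose = NULL, ...) {
  if (is.null(newdose)) newdose <- object$table$dose
  if (object$covariate == "log10")
    lethality_probability(object$params, newdose)
  else
    inv_link(object$params$beta0 + object$params$beta1 * newdose,
             object$params$link)
}

#' Simulate replicate outcome tables from a fitted dose-response model
#'
#' @param object a `"dose_fit"`.
#' @param nsim number of replicate tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` [dose_table()]s with binomial death counts.
#' @export
simulate.dose_fit <- function(object, nsim = 1, seed = NULL, ...) {
  p <- predict(object)
  tab <- object$table
  with_seed(seed, replicate(nsim, simplify = FALSE,
    dose_table(tab$dose, tab$n, stats::rbinom(nrow(tab), tab$n, p))))
}

#' Posterior predictive deviance p-value
#'
#' For each retained posterior draw, simulates a replicate outcome table
#' from the binomial model at that draw, computes the deviance of the
#' replicate and of the observed data under the same draw, and returns
#' the fraction of draws in which the replicate deviance exceeds the
#' observed deviance. Values near 0 indicate the model cannot reproduce
#' the observed discrepancy; calibrated data give values away from the
#' extremes.
#'
#' @param chain a [run_dram()] result whose columns are `(beta0, beta1)`,
#'   or a numeric matrix of draws.
#' @param table the observed [dose_table()].
#' @param seed optional integer seed for the replicate simulations.
#' @param link link function shared by all draws.
#' @param burn fraction of initial draws to discard (defaults to the
#'   chain's own burn-in fraction, or 0 for plain matrices).
#' @return A probability in `[0, 1]`.
#' @export
posterior_predictive_p <- function(chain, table, seed = NULL, link = "logit",
                                   burn = NULL) {
  draws <- chain_draws(chain, burn)
  if (nrow(draws) < 1L) abort_validation("chain is empty")
  stopifnot(inherits(table, "dose_table"))
  with_seed(seed, {
    exceed <- vapply(seq_len(nrow(draws)), function(i) {
      par <- link_params(draws[i, 1], draws[i, 2], link)
      p <- lethality_probability(par, table$dose)
      rep_tab <- table
      rep_tab$deaths <- stats::rbinom(nrow(table), table$n, p)
      dose_deviance(par, rep_tab) > dose_deviance(par, table)
    }, logical(1))
    mean(exceed)
  })
}
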