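# ionferm

Statistical analysis of heavy-ion-beam mutagenesis and butyrate
fermentation experiments in R.

Heavy-ion (¹²C⁶⁺) irradiation is used to breed *Clostridium
tyrobutyricum* mutants with improved butyric-acid production and acid
tolerance. Characterizing such campaigns requires a chain of distinct
statistical analyses, and `ionferm` packages that chain end to end for
bioprocess statisticians and strain-engineering groups:

* **Irradiation lethality.** Per-dose death counts are modelled as
  `y_i ~ Binomial(n_i, p(x_i))` with
  `logit p(x) = β₀ + β₁·log₁₀(x)` (probit and complementary log-log
  links are also available). The model is fitted by maximum likelihood
  and sampled with a **delayed-rejection adaptive-Metropolis (DRAM)**
  chain under a flat prior; fit quality is judged by the deviance
  `D = −2 log L` and its posterior predictive p-value, and the fitted
  curve is reported with 50/90/95/99% posterior predictive envelopes.
* **Batch growth kinetics.** Biomass follows the logistic model
  `dx/dt = μₘ x (1 − x/xₘ)`, i.e.
  `x(t) = xₘ / (1 + ((xₘ−x₀)/x₀) e^{−μₘ t})`. The linearization
  `ln(x/(xₘ−x)) = μₘ t + ln(x₀/(xₘ−x₀))` is fitted by least squares;
  a Bayesian fit co-samples the Gaussian error variance (the `s2chain`)
  with DRAM.
* **Mutant screening.** Strain rating matrices (maximum biomass,
  butyrate, hydrogen, butyrate/acetate ratio) are analysed by
  inverse-variance **weighted PCA** with orthonormalized loadings and
  ranked by **Hotelling's T²** distance from the population centre.
* **pH trajectories.** Serum-bottle pH series are filtered with a
  one-dimensional linear-Gaussian **Kalman filter** (random-walk state,
  gain `K = P/(P+R)`), the exact minimum-mean-squared-error estimator.
* **Fermentation performance.** Batch summaries: final titres, B/A
  ratio, OD600 → dry-cell-weight conversion (0.396 g/L per OD unit),
  glucose consumption, butyrate yield, and the MTT growth-delay
  survival fraction `2^(−T_delay/T_doubling)`.
* **Synthetic data.** Seeded generators emulate every input kind with
  the distributional structure the models assume, calibrated to the
  published endpoint values, so the whole chain is testable without
  access to raw fermentation records.

## Worked example

```r
library(ionferm)

# 16-dose irradiation outcome table shipped with the package
tab <- table1_dose_response()
fit <- fit_dose_response(tab)
fit
#> Binomial dose-response fit (logit link, log10-dose covariate)
#>    beta0    beta1
#> -11.1050   6.8753
#> log-likelihood: -1458   deviance: 2917

# DRAM posterior for (beta0, beta1), 5000 steps, flat prior
chain <- dose_posterior_chain(tab, fit, n_steps = 5000, seed = 1)
summary(chain)
#> DRAM chain diagnostics (4000 retained draws, acceptance 0.861)
#>           mean     sd     2.5%    97.5%
#> beta0 -11.1030 0.0761 -11.2591 -10.9617
#> beta1   6.8739 0.0452   6.7896   6.9656

# logistic growth: noise-free curve for the 10 g/L-butyrate culture
s <- gen_growth_curve("butyrate10", noise_sd = 0)
fit_growth_linear(s, x_m = 1.543)
#> Linearized logistic growth fit (x_m fixed at 1.543 g/L)
#>   mu_m      = 0.1934 1/h
#>   intercept = 0.1155
#>   implied x0 = 0.816 g/L

# batch fermentation endpoints of the default pH 5.0 scenario
summarize_fermentation(gen_fermentation("pH5.0", noise = FALSE))
#> Batch fermentation summary
#>   final butyrate:    57.63 g/L
#>   final acetate:     9.295 g/L
#>   B/A ratio:         6.2
#>   max biomass:       1.544 g/L DCW
#>   glucose consumed:  140 g/L
#>   butyrate yield:    0.4116 g/g
```

The dose–response fit says lethality climbs from about 5% at 15 Gy to
91% at 90 Gy, with a steep slope of 6.9 logits per decade of dose; the
tight posterior (sd ≈ 0.08 and 0.05) reflects the ~6000 cells per dose.
The growth fit recovers the maximum specific growth rate 0.1934 1/h and
initial biomass 0.816 g/L exactly on a noise-free curve, and the
fermentation summary reproduces the calibrated pH 5.0 endpoints
(57.63 g/L butyrate at a butyrate/acetate ratio of 6.2).

A full deterministic pipeline over all stages:

```r
run_pipeline(pipeline_config(seed = 1), outdir = "out")
```

writes fixtures, fits, chains, envelopes, filtered series and summaries
under `out/` with a manifest and a resolved-config copy.

## Package layout

* `R/` — implementation; S3 fitting functions (`fit_dose_response`,
  `fit_growth_linear`, `fit_growth_bayes`, `weighted_pca`,
  `kalman_filter`) return classed objects with `print`, `summary`,
  `coef`, `predict`, `simulate`, `residuals` and `plot` methods as each
  model admits.
* `inst/extdata/table1_dose_response.csv` — packaged irradiation table.
* `vignettes/ionferm-methods.Rmd` — models, assumptions, calibration
  and numerical choices.
* `tests/testthat/` — unit, property and acceptance suites with
  independent oracles (fine-grid likelihood maximization, Runge–Kutta
  integration, closed-form Bayesian updates).
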