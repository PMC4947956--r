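---
title: "Models and methods in ionferm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ionferm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionferm)
```

`ionferm` implements the statistical chain used to characterize
heavy-ion-irradiated *Clostridium tyrobutyricum* mutants: binomial
dose–response modelling of irradiation lethality, logistic batch-growth
kinetics, weighted-PCA screening of strain rating matrices, Kalman
filtering of pH trajectories, and batch fermentation summaries. This
vignette records the models, their assumptions, the tunable parameters,
and the numerical and design choices behind the implementation.

## Binomial dose–response model

At each absorbed dose $x_i$ (Gy), $n_i$ cells are irradiated and $y_i$
die, modelled as $y_i \sim \mathrm{Binomial}(n_i, p(x_i))$ with

$$\operatorname{logit} p(x) = \beta_0 + \beta_1 \log_{10} x.$$

The covariate is $\log_{10}$ dose because the experimental record
tabulates log dose and the dose range (15–90 Gy) spans close to a
decade; a raw-dose covariate is available via `covariate = "raw"`, and
probit and complementary log-log links via `link`. The log-likelihood
*includes* the binomial coefficient term
$\sum_i \log \binom{n_i}{y_i}$, so the reported deviance
$D = -2\log L$ is an absolute quantity, comparable across analyses; the
term does not affect the maximizer. Boundary cells are handled
explicitly: a fitted probability of exactly 0 (or 1) that conflicts
with the observed counts yields $-\infty$ log-likelihood rather than an
error, because the packaged table legitimately contains a 100%-lethal
row at 90 Gy.

`fit_dose_response()` maximizes the likelihood by iteratively
reweighted least squares (via `stats::glm`), flags complete separation
as a named error, and returns the observed-information covariance. The
test suite checks the fit against an independent two-dimensional
fine-grid likelihood maximizer; the grid zoom is deliberately gentle
(factor 0.45 per stage) because the $(\beta_0,\beta_1)$ likelihood
ridge is strongly diagonal and aggressive axis-aligned shrinking can
strand a grid search off the ridge.

Model criticism uses the posterior predictive deviance check: for each
posterior draw, a replicate table is simulated and the fraction of
draws whose replicate deviance exceeds the observed deviance is
reported. Values near 0 flag overdispersion relative to the binomial
model; data simulated from the model itself give values comfortably
inside (0.2, 0.8) on average.

## DRAM sampler

Posteriors are sampled with delayed-rejection adaptive-Metropolis
random-walk MCMC, written in the package:

* initial proposal covariance $2.38^2/d \times C_0$, where $C_0$ is the
  MLE covariance when available and the identity otherwise;
* adaptation of the proposal covariance from the full chain history
  every 100 steps (with a $10^{-10}$ diagonal regularizer);
* one delayed-rejection stage: after a first rejection, a proposal at
  1/5 the scale is tried with the standard two-stage acceptance
  correction;
* default chain length 5000 steps, matching the study's setting, with
  the first 20% discarded by summaries and envelopes (burn-in is not
  stated in the source study; 20% is configurable via
  `dram_options()`).

Priors are likewise unstated in the study; the package uses flat
improper priors on $(\beta_0, \beta_1)$ and on growth parameters within
their positivity bounds, and a vague inverse-gamma(0.01, 0.01) prior on
the Gaussian error variance — the common defaults of DRAM toolboxes.
For Gaussian-noise regressions the error variance is co-sampled
conjugately each step (`sample_error_variance()`), producing the
`s2chain` whose square root is the chain of the error standard
deviation.

Delayed rejection raises the overall acceptance rate well above the
0.2–0.4 typical of plain Metropolis (small second-stage steps are often
accepted); correctness is therefore judged by moments, not acceptance:
on a standard Gaussian target the grand mean over 50 seeded 5000-step
chains is within 0.05 of 0 and the variance within 0.1 of 1, and a
correlated 2-D Gaussian is recovered to 5%.

`predictive_envelope()` evaluates a model function over a random subset
of draws and returns central quantile bands (defaults 50/90/95/99%).
Observation-level envelopes add one noise realization per draw —
Gaussian with the s2chain, or user-supplied (e.g. binomial). The subset
may exceed the chain length, in which case draws are bootstrapped with
replacement; large subsets (the acceptance analysis uses 20000) make
envelope quantile-estimation noise negligible, which matters because
coverage is concave in the bound positions and noisy bounds bias
coverage downward.

## Logistic growth kinetics

Biomass follows $dx/dt = \mu_m x (1 - x/x_m)$ with closed form
$x(t) = x_m / (1 + ((x_m - x_0)/x_0)\,e^{-\mu_m t})$, implemented in
the overflow-safe form above and verified against fourth-order
Runge–Kutta integration to $10^{-6}$. The linearization
$\ln(x/(x_m - x)) = \mu_m t + \ln(x_0/(x_m - x_0))$ is fitted by
ordinary least squares; the slope is $\mu_m$ and the intercept identity
gives the implied $x_0 = x_m/(1 + e^{-\mathrm{intercept}})$. $x_m$ is
fixed at the observed plateau by default (0.1% above the maximum
reading when unspecified) and may be sampled as a free parameter in the
Bayesian fit.

Two calibrated parameter sets are built in as `growth_scenario()`s:
$(x_0, x_m, \mu_m) = (0.816, 1.543, 0.1934)$ for the 10 g/L-butyrate
culture and $(0.553, 1.386, 0.1434)$ for the 12 g/L culture. On
noise-free curves the linearized fit recovers the slopes exactly (the
acceptance suite checks 8+ decimals). Note the published intercepts
(−0.0732, −0.0547) are not consistent with the published $x_0$ values
under the intercept identity (they imply 0.743 and 0.674 g/L); the
package always reports the identity-implied $x_0$ and makes no claim
about the discrepancy.

**Limitation of the linearization.** Near the plateau,
$\ln(x/(x_m - x))$ amplifies additive measurement noise without bound,
and readings at or above $x_m$ leave the transform's domain entirely
(they are dropped with a warning). With noise sd 0.02 g/L on a design
whose readings stay clearly below the plateau ($x_0 = 0.08$,
$x_m = 1.5$, 0–30 h) the mean recovered slope is within 1% of truth
over 200 replicates; on a design that spends most of its span within
two noise-sd of the plateau, plain OLS on the transformed data is
severely biased. Practitioners should truncate the fitting window to
the growth phase, or use the Bayesian fit, which works on the original
scale and has no such pathology.

## Weighted PCA screening

Ratings of screened strains over (maximum biomass, butyrate, hydrogen,
B/A ratio) carry different units, so PCA uses inverse-variance weights
by default: columns are centered, scaled by $\sqrt{w_j}$, and the
covariance of the scaled data is eigendecomposed. This makes the
analysis invariant to per-column unit changes and reduces to
correlation-matrix PCA. The coefficient matrix expressed on the
original variables is not orthonormal because of the weighting; both it
(`loadings_raw`) and the orthonormalized loadings are exposed, the
latter satisfying $L^\top L = I$ to $10^{-10}$. Eigenvector signs are
fixed by making each loading's largest-magnitude element positive.
Outlyingness is ranked by Hotelling's
$T^2_i = \sum_{j \le k} s_{ij}^2/\lambda_j$ with $k = 3$ components by
default; no F-distribution cutoff is applied because the study reports
a ranking, not a test.

The synthetic screening population is calibrated so that the
inverse-variance weighted analysis carries 62% of variance on the first
two components and 93% on the first three: the correlation structure is
built from eigenvalue fractions (0.31, 0.31, 0.31, 0.07) through a
Hadamard rotation, then scaled to per-variable sds (1.0, 1.5, 0.8,
1.2). A consequence worth recording: with those eigenvalue fractions
the correlation matrix's smallest eigenvalue is 0.28, which caps the
achievable pairwise correlation at about 0.24 — a 0.9-level pairwise
correlation is mathematically incompatible with the printed variance
fractions, and the generator prioritizes the fractions, which the tests
rely on. Seven outlier rows (defaulting to the campaign's strain
numbers 8, 78, 150, 203, 221, 278, 323) are shifted by 4 sd per
variable, hydrogen downward; contamination at this level inflates the
leading sample eigenvalues, so the population-calibration tests use
uncontaminated samples.

## Kalman filtering of pH

The study describes a one-dimensional linear system with zero-mean
Gaussian measurement error but no state model; the package adopts the
minimal choice consistent with that description, a random walk:
predict leaves the mean unchanged and adds $Q$ to the variance; update
applies the gain $K = P/(P+R)$. A local-linear-trend state (level +
slope) is available behind `state = "local-trend"` and tracks sustained
declines with less lag. $R = 0$ is handled as the exact-measurement
limit ($K = 1$), not a division failure. Because the study reports no
noise magnitudes, the defaults estimate $Q$ and $R$ as half the lag-1
difference variance of the observed series each, with the state
initialized at the first observation.

Filter correctness is tested against closed forms: the batch Bayesian
running mean when $Q = 0$, and the steady-state variance
$P^* = (-Q + \sqrt{Q^2 + 4QR})/2$ solving
$P^* = (P^*+Q)R/(P^*+Q+R)$. On the model-consistent simulation (flat
trend, random-walk process noise, true $Q, R$) the filter beats the raw
measurements in MSE in 100 of 100 seeded runs, as the MMSE property
requires; the data-driven defaults also win 100/100 on the default
trend-bearing scenario.

## Synthetic-data calibration

The study deposits no raw growth, pH or fermentation series, so the
generators are calibrated only to the printed endpoint and
turning-point values; everything else is a documented modelling choice
made once.

* **Dose–response**: binomial sampling at the 16 experimental doses
  with the recorded per-dose totals (the packaged
  `table1_dose_response.csv`; its 15 Gy row records 600 deaths).
* **pH trajectories** (2-h sampling over 120 h): piecewise-linear
  latent skeletons with one transient rise — the acid-to-solvent
  detoxification bump. pH 5.0: 5.00 → 4.60 at 30 h → peak 4.75 at
  42 h → 4.20 at 120 h. pH 4.5: 4.50 → 4.25 at 20 h → peak 4.40 at
  28 h → 4.10 at 120 h (the total drop of 0.4 is taken at face value;
  the printed terminal value for this arm is internally inconsistent
  with its stated starting point and drop). Process noise is a random
  walk (sd 0.01 per step) on the latent pH; measurement noise is
  i.i.d. Gaussian (sd 0.05). Neither magnitude is stated in the study;
  both are free parameters of the scenario.
* **Fermentation** (pH 5.0: 150 g/L glucose over 200 h; pH 4.5:
  60 g/L over 110 h): butyrate and acetate follow logistic-in-time
  production ramps normalized so the final sample equals the calibrated
  endpoint exactly — 57.63 g/L butyrate and B/A 6.2 at pH 5.0, B/A 2.9
  at pH 4.5 (acetate endpoint 8.0 g/L, close to the pH 5.0 value of
  9.30 and within the glucose budget at a plausible overall
  acid-per-glucose conversion of ~0.66 g/g). Glucose decreases in
  proportion to total acid formed; OD600 follows a logistic ramp
  (maximum 3.9 at pH 5.0, 2.8 at pH 4.5); cumulative gas tracks total
  acid in arbitrary units, since hydrogen is reported only
  qualitatively. Noise is multiplicative Gaussian (cv 2%) on the
  concentration channels, and acts on per-step increments (truncated at
  zero) for glucose and gas so monotonicity survives any seed.

Every generator is bit-reproducible under an integer seed, restores the
caller's RNG state, and truncates concentrations at zero. What passing
tests show, therefore, is that the analysis chain recovers the
structure this generator encodes — smooth single-phase kinetics,
homoskedastic Gaussian or exact binomial noise, no batch effects,
no instrument drift, no missing samples. Real fermentation records
violate several of these (biphasic metabolism, heteroskedastic assays,
irregular sampling), and the tests make no claim about them.

## Problem sizes and numerical choices

Test and acceptance runs use the study's chain length (5000 steps)
throughout; heavier checks are sized for precision at reasonable cost:
50 seeded chains for the Gaussian-moment check, 200 replicate tables
for parameter recovery, 100 seeded runs for the filter-vs-measurement
comparison, and 25 simulated datasets × 100 replicate observations for
the predictive-envelope coverage estimate. The coverage quantity is the
*marginal* (dataset-averaged) coverage: coverage conditional on a
single simulated dataset has a standard deviation of about 3 percentage
points (the posterior location error induced by that dataset's binomial
noise shifts the whole envelope), so single-dataset estimates scatter
widely around the nominal level even though the envelope is perfectly
calibrated on average; a 60-dataset calibration run measures the
marginal coverage at 94.97%.

Other numerical choices: the logistic closed form is evaluated in the
overflow-safe parameterization; eigendecompositions use
`eigen(symmetric = TRUE)` with eigenvalues clipped at zero; Hotelling's
$T^2$ refuses components with non-positive eigenvalues; ties in outlier
ranking preserve input order (stable sort); and validation failures
throw conditions of class `ionferm_validation_error` so callers can
distinguish data problems from bugs.
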