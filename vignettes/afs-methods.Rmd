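---
title: "Modelling age at first sex with reporting-bias adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling age at first sex with reporting-bias adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afstrend)
```

## The problem

Age at first sex (AFS) is collected retrospectively in repeated
cross-sectional household surveys, in completed integer years, with a
"never had sex" option. Three features complicate trend estimation:

1. **Censoring.** Respondents who have not yet debuted are right-censored
   at their interview age; naive medians are biased downward for young
   cohorts.
2. **Interval censoring.** A reported age $a$ only locates the true event
   time in $[a, a+1)$.
3. **Age-at-report bias.** The same birth cohort reports systematically
   different AFS when re-surveyed at different ages (social-desirability
   and recall effects). Comparing a cohort's proportion reporting debut
   before 18 across successive surveys (`prop_before_age()`) makes this
   visible directly.

The package estimates the full AFS distribution per birth cohort while
separating the true cohort trend from the reporting bias, exploiting that
successive surveys observe the *same* cohorts at *different* ages.

## The model

Each cohort's AFS follows a log-skew-logistic distribution,

$$S(t) = 1 - \left[1 + (\lambda t)^{-p}\right]^{-\gamma},$$

with rate $\lambda$, shape $p$ and skewness $\gamma$; $\gamma = 1$ is the
log-logistic. This family allows the asymmetric, non-monotone debut hazard
seen in empirical AFS data (slow rise to the late teens, then a plateau and
decline) which gamma, log-normal and Weibull-type families cannot express.
The median is $\lambda^{-1}(2^{1/\gamma}-1)^{-1/p}$.

Two printed-source caveats are deliberate implementation choices: the
skew-logistic density is implemented as the exact derivative of its CDF
(the version typeset in our source material drops a factor of $p$ in the
exponent), and the hazard is always computed as $f/S$ rather than from a
separately typeset expression.

The rate varies by record through a log-scale regression
$$\lambda_i = \exp(-\eta_i), \qquad
  \eta_i = \beta_0 + f(\mathrm{bch}_i) + b(\mathrm{age}_i),$$
where $f$ is the birth-cohort trend and $b$ the age-at-report bias, each
absent, linear, or a first-order random walk (RW1). The five standard
structures are labelled M1 (intercept) through M5 (RW1 cohort + RW1 age).
Shape and skewness are shared across cohorts so that heavily censored
recent cohorts borrow strength from completed ones.

Records enter a weighted interval-censored pseudo-likelihood with survey
design weights rescaled to each survey's Kish effective sample size
$n_\mathrm{eff} = (\sum w)^2/\sum w^2$. The weights multiply the
*log*-likelihood terms (pseudo-likelihood exponents); a literal reading in
which weights multiply the likelihood as constants would make them
inert, so the exponent reading is used.

**Priors.** Standard normal on the intercept and linear slopes; iid
$N(0, \tau^{-1})$ on RW1 increments with a penalised-complexity prior on
each precision, $P(\sigma > u) = \alpha$ with defaults $u = 1$,
$\alpha = 0.01$ (a weak choice for effects on a log scale, configurable);
weakly-informative standard normals on $\log p$ and $\log\gamma$
(initialised at $p = 6$, $\gamma = 0.5$). The PC hyperparameters and the
shape/skewness priors are package defaults — the source material does not
state them.

**Constraints.** Each RW1 component is parameterised by its first
differences and centred, so $\sum f = \sum b = 0$ holds exactly by
construction. For reporting, the bias curve is re-centred so that
$b(\text{reference age}) = 0$ (default reference age 23, taken as the age
at which reporting is accurate) with the offset absorbed into $\beta_0$;
this affine shift leaves the likelihood unchanged, which reconciles the
sum-to-zero estimation constraint with the reference-age convention.

## Inference

`fit_afs()` is empirical Bayes with two levels:

* **Inner:** at fixed RW1 precisions, the penalised log-likelihood is
  maximised over $(\beta_0, \text{increments}, \log p, \log\gamma)$ by
  damped Newton with analytic gradients and an analytic Hessian
  (Armijo backtracking; Levenberg damping if the Hessian is locally
  indefinite).
* **Outer:** the log-precisions maximise the Laplace-approximated marginal
  posterior, $\log\pi(\hat\theta,\tau) - \tfrac12\log\det H + \text{const}$,
  by Nelder-Mead over (at most) two dimensions.

A *joint* mode over effects and precisions — superficially simpler — does
not exist: the joint density is unbounded along (effects $\to 0$,
precision $\to\infty$), and in testing a joint optimiser reliably ran the
precision to any imposed bound and flattened the fitted trend to a tenth
of its true size in every scenario. Integrating the latent effects out
via the Laplace approximation (as latent-Gaussian engines such as TMB and
INLA do) removes the spike; this package's design decision follows that
route. Uncertainty is then a Gaussian approximation at the conditional
mode with the precisions held at their estimates — an empirical-Bayes
approximation that understates hyperparameter uncertainty; credible
intervals for quantities dominated by the latent effects are the intended
use. `posterior_draws()` draws from this Gaussian; reconstruction from
increments keeps every draw exactly sum-to-zero. Equal-tailed 95%
intervals use 1000 draws by default.

Numerical details: multiple jittered inner starts (3 by default, seeded);
inner convergence at relative gradient norm $10^{-5}$ (non-convergence is
flagged on the returned object, not an error); interval probabilities are
computed on the log scale via `log1p`/`expm1` with a $10^{-300}$ floor
against underflow (floored terms are counted); identical (cohort, age,
outcome) records are collapsed with summed weights — exact, since the
likelihood is linear in the weights — and cells are sorted so the fit is
bitwise record-order invariant.

## Model comparison

`kfold_elpd()` implements K-fold (default 10) cross-validated expected log
pointwise predictive density with folds stratified by survey so every
training set retains all surveys, the fold partition shared across
specifications in `compare_models()`, and each held-out record contributing
$\log \frac1S \sum_s p(y_i \mid \theta_s)$ with $S$ posterior draws from
the training fit (default 1000). The held-out density is the record's
interval or censoring probability raised to its scaled weight, consistent
with training. Tables report differences to the best model (best = 0),
matching the usual presentation.

## The simulation world

`afs_scenario()` states the generator's world; its defaults are the
conditions of the validation design and are not adjusted per run:

* population of $10^6$ (desk-scale studies use $10^5$; only ~1000
  individuals per survey are observed, so this only widens Monte-Carlo
  noise negligibly) with birth years uniform on 1940–2005;
* true median AFS linear in birth year: constant 17, increasing 15 to 19,
  or decreasing 19 to 15 across the span (only the endpoints are given by
  the design; linear interpolation is the package's choice);
* true shape $p = 8$, skewness $\gamma = 0.6$, chosen so the
  inter-quartile range is roughly 15–20 years at median 17 (the validation
  design does not state its values; these are fixed once here);
* $k = 2,\dots,5$ surveys five years apart ending 2020, each sampling 1000
  adults aged 15–49 without replacement with selection probability
  $\propto e^{-0.03(\mathrm{age}-15)}$, a monotone-declining stand-in for
  a typical high-fertility adult age structure (the reference table is not
  available; the rate is configurable);
* reporting bias as an additive offset on $\eta$ by age at interview.
  Magnitudes are not stated in the design, so the package fixes:
  type I $-0.05$ up to age 20, through 0 at 23, to $+0.04$ from 32
  (young respondents report earlier, older respondents later); type II
  $+0.05$ below 25 declining to 0 at 30 (young respondents report older,
  no bias at 30+). At median 17 these shift reported medians by roughly
  0.5–0.9 years. The reported AFS is an **independent** redraw from the
  biased distribution (a rank-preserving redraw is available via
  `quantile_matched = TRUE`), floored to completed years, with draws
  reaching the interview age recorded as right-censored.

What a green simulation test does establish: that the fitting machinery
separates trend from age-at-report bias under the stated world, with the
stated sample sizes and bias shapes. What it does not establish: robustness
to bias patterns outside the additive-in-$\eta$ family (e.g. temporal
reporting shifts affecting all ages), to informative sampling beyond age
structure, to cluster-correlated designs, or to sex/country differences in
bias shape — real-data features the generator deliberately omits.

`run_study()` repeats simulate-and-fit, reporting the estimated change in
median AFS between the 1985 and 2005 cohorts, the error for the 2005
cohort, the mean error across 1985–2005, and the fraction of replicates
detecting a change (correct-sign change exceeding half a year). Study
fits use a single optimiser start: with analytic derivatives and a convex
inner problem near the mode, jittered starts change study metrics by less
than Monte-Carlo noise, at three times the cost.

## Descriptive diagnostics

The weighted Kaplan–Meier estimator (`km_survival()`) places an event
reported at age $a$ at its left endpoint and censors never-had-sex
respondents at interview age; its discrete hazard
(`km_discrete_hazard()`) is the per-age event probability, used as the
visual check that motivates the distribution family. Kernel-smoothed
hazard estimation is intentionally out of scope — the discrete hazard
carries the same diagnostic content. Proportion-type summaries use a
normal approximation on the cell's Kish effective sample size; full
design-based clustered variance is a documented limitation since the
generic record schema carries no cluster labels.

## Known limitations

* Empirical-Bayes intervals ignore precision uncertainty (above).
* With a single survey, linear cohort and age effects are exactly
  collinear ($\mathrm{bch} = \mathrm{year} - \mathrm{age}$); the model is
  then identified only through the priors. Two or more surveys are
  required for meaningful bias adjustment, three or more for reliable
  trend detection — the point the simulation study quantifies.
* Covariates other than birth cohort and age at report (residence,
  education, ...) are out of scope, as is pooling across
  countries/sexes.
* The reference age at which reporting is assumed unbiased is an
  assumption; mis-specifying it leaves the *trend* estimate intact but
  shifts estimated median levels (this is itself verified in the
  acceptance suite).
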