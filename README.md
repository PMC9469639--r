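# afstrend

Estimating trends in **age at first sex (AFS)** from repeated
cross-sectional household surveys, adjusting for **age-at-report bias** —
the systematic dependence of retrospectively reported AFS on how old the
respondent is when asked.

AFS is a routine indicator for HIV/STI programme monitoring, usually taken
from surveys such as the DHS. Reports are censored (some respondents have
not yet debuted), interval-censored (integer completed years), and biased:
the same birth cohort reports different AFS distributions when re-surveyed
five years later. `afstrend` is for epidemiologists and demographers who
want cohort trends in the full AFS distribution with those three problems
handled jointly.

## Model

Per birth cohort, AFS follows the three-parameter log-skew-logistic
distribution

    S(t) = 1 − [1 + (λt)^(−p)]^(−γ),    median = λ^(−1) (2^(1/γ) − 1)^(−1/p),

whose non-monotone hazard matches empirical debut rates (γ = 1 gives the
log-logistic). The record-level rate is λ_i = exp(−η_i) with

    η_i = β0 + f(birth cohort_i) + b(age at report_i),

f the true cohort trend and b the reporting-bias curve, each none / linear /
first-order random walk (model structures M1–M5), with sum-to-zero
constraints, penalised-complexity priors on the random-walk precisions, and
b re-centred to zero at a reference age (default 23) where reporting is
assumed accurate. Records enter an interval-censored pseudo-likelihood with
design weights rescaled to each survey's Kish effective sample size.
Fitting is empirical Bayes: damped-Newton conditional modes with analytic
derivatives, and random-walk precisions estimated by Laplace-approximated
marginal posterior. Structures and distributions are compared by K-fold
cross-validated ELPD, and a built-in multi-survey simulation study measures
trend recovery under configurable bias patterns. See the methods vignette
(`vignettes/afs-methods.Rmd`) for the full account.

## Worked example

Simulate three surveys (2010/2015/2020, 1000 respondents each) from a world
where the true median AFS declines from 19 (1940 cohort) to 15 (2005
cohort) and respondents under 30 over-report their AFS ("type II" bias),
then fit the bias-adjusting model M5:

```r
library(afstrend)
sc <- afs_scenario(trend = "decreasing", bias_type = "typeII",
                   n_surveys = 3, pop_size = 1e5)
records <- simulate_surveys(sc, seed = 42)
fit <- fit_afs(records, afs_spec_m("M5"), seed = 1)
print(fit)
#> AFS model fit (logskewlogistic, cohort: rw1, age: rw1)
#>   n = 3000 | log-posterior = -7997.958 | converged: TRUE
#>   shape p = 8.21 | skewness gamma = 0.5701
#>   baseline median AFS = 16.51 years

draws <- posterior_draws(fit, n_draws = 1000, seed = 2)
med <- median_afs_by_cohort(fit, draws)
subset(med, birth_year %in% c(1985, 1995, 2005))
#>    birth_year median lower upper
#> 25       1985   16.6  16.2  17.1
#> 35       1995   16.2  15.8  16.6
#> 45       2005   15.9  15.2  16.6
```

The fitted cohort medians (16.6 → 15.9, with 95% credible intervals from
1000 Gaussian-approximation draws) track the true values (16.2 → 15.0)
despite the upward reporting bias in young respondents — with only three
surveys the decline is detected but its magnitude somewhat understated,
exactly the behaviour the simulation study quantifies. `bias_curve(fit,
draws)` returns the estimated b(age) − b(23) curve, and
`compare_models(records, list(M3 = afs_spec_m("M3"), M5 = afs_spec_m("M5")))`
reproduces the cross-validation evidence that the age-at-report term
improves prediction.

Model-free diagnostics: `prop_before_age()` (within-cohort % reporting
debut before 18 across surveys — the raw fingerprint of reporting bias),
`km_survival()` / `km_discrete_hazard()` (weighted product-limit estimate
and its discrete hazard). A small synthetic example dataset ships in
`inst/extdata/synthetic_records.csv`.

Command line: `fit`, `summarize`, `cv`, `simulate`, `study`, `describe`
subcommands via

```sh
Rscript -e 'afstrend::afs_cli()' simulate --scenario scenario.json --out records.csv --seed 1
```

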