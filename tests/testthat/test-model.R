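# Weights, constraints, likelihood, priors and their derivatives.

test_that("Kish effective sample size", {
  expect_equal(kish_neff(c(1, 1, 1, 1)), 4)
  expect_equal(kish_neff(c(1, 3)), 1.6)
  for (w in c(0.2, 1, 7)) expect_equal(kish_neff(rep(w, 9)), 9)
  expect_error(kish_neff(numeric(0)), "empty")
  expect_error(kish_neff(c(1, -1)), "positive")
})

test_that("weight scaling per survey", {
  r <- toy_records()
  r$design_weight <- c(1, 3, 1, 3)
  r$survey_id <- c("a", "a", "b", "b")
  out <- scale_weights(r)
  expect_equal(out$scaled_weight, c(0.4, 1.2, 0.4, 1.2))
  expect_equal(sum(out$scaled_weight[1:2]), kish_neff(c(1, 3)))
  # independent per survey, invariant to record order and overall rescaling
  perm <- sample(nrow(r))
  expect_equal(scale_weights(r[perm, ])$scaled_weight, out$scaled_weight[perm])
  r2 <- r; r2$design_weight[r2$survey_id == "a"] <- r$design_weight[1:2] * 50
  expect_equal(scale_weights(r2)$scaled_weight, out$scaled_weight)
  # single record: w* = 1
  expect_equal(scale_weights(r[1, ])$scaled_weight, 1)
  # equal weights pass through unchanged
  expect_equal(scale_weights(toy_records())$scaled_weight, rep(1, 4))
})

test_that("sum-to-zero projection", {
  expect_equal(project_sum_to_zero(c(1, 2, 3)), c(-1, 0, 1))
  v <- c(-2, 0.5, 1.5)
  expect_equal(project_sum_to_zero(v), v)
  expect_equal(project_sum_to_zero(project_sum_to_zero(c(4, -1, 9))),
               project_sum_to_zero(c(4, -1, 9)))
})

test_that("record validation enforces the schema contracts", {
  r <- toy_records()
  expect_silent(validate_records(r))
  r2 <- r; r2$reported_afs[1] <- NA
  out <- validate_records(r2)
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_dropped_unknown"), 1)
  r3 <- r[, -3]
  expect_error(validate_records(r3), "birth_year")
  r4 <- r; r4$reported_afs[1] <- 31L
  expect_error(validate_records(r4), "exceeds")
  r5 <- r; r5$age_at_report[1] <- 35L
  expect_error(validate_records(r5), "inconsistent")
})

test_that("log-likelihood matches direct survival-function evaluations", {
  spec <- afs_spec("loglogistic", "none", "none")
  # single censored record with S(T) = 0.8: rate chosen by inverting F
  r <- toy_records()[4, ]          # censored at age 20
  rate <- (0.2^(-1) - 1)^(-1 / 8) / 20   # F(20) = 0.2 at shape 8, skew 1
  ll <- log_likelihood(r, list(beta0 = -log(rate), p = 8, gamma = 1), spec)
  expect_equal(ll, log(0.8), tolerance = 1e-12)
  # single event record T = 16 at (1/17, 8, 1)
  r <- toy_records()[2, ]; r$reported_afs <- 16L
  ll <- log_likelihood(r, list(beta0 = log(17), p = 8, gamma = 1), spec)
  direct <- log(plsl(16, 1 / 17, 8, 1, lower.tail = FALSE) -
                  plsl(17, 1 / 17, 8, 1, lower.tail = FALSE))
  expect_equal(ll, direct, tolerance = 1e-12)
  # linear in the scaled weights
  r <- scale_weights(validate_records(toy_records()))
  pars <- list(beta0 = log(17), p = 8, gamma = 0.6)
  ll1 <- log_likelihood(r, pars, spec)
  r$scaled_weight <- r$scaled_weight * 2
  expect_equal(log_likelihood(r, pars, spec), 2 * ll1, tolerance = 1e-12)
})

test_that("likelihood is invariant to shifting level between beta0 and f", {
  recs <- sim_fixture("constant", "none", 2)
  spec <- afs_spec(cohort_effect = "rw1")
  dat <- afstrend:::prepare_fit_data(recs, spec)
  f <- sin(seq_along(dat$cohorts)) * 0.05
  pars1 <- list(beta0 = log(17), f = f, p = 8, gamma = 0.6)
  pars2 <- list(beta0 = log(17) - 0.3, f = f + 0.3, p = 8, gamma = 0.6)
  expect_equal(log_likelihood(recs, pars1, spec),
               log_likelihood(recs, pars2, spec), tolerance = 1e-10)
})

test_that("linear predictor and the scale-to-rate mapping", {
  spec <- afs_spec("loglogistic", "none", "none")
  r <- toy_records()
  pars <- list(beta0 = log(17), p = 8, gamma = 1)
  eta <- linear_predictor(r, pars, spec)
  expect_equal(eta, rep(log(17), 4))     # M1: intercept only
  # rate = exp(-eta) so the skew-1 median is exp(eta)
  expect_equal(lsl_median(exp(-eta[1]), 8, 1), 17)
  # +0.1 on the age effect multiplies the implied median by exp(0.1)
  spec2 <- afs_spec(age_effect = "rw1", age_range = c(20, 30))
  b <- rep(0, 11)
  m0 <- lsl_median(exp(-linear_predictor(r[1, ], list(beta0 = log(17), b = b,
    p = 8, gamma = 1), spec2)), 8, 1)
  b[11] <- 0.1                            # record 1 reports at age 30
  m1 <- lsl_median(exp(-linear_predictor(r[1, ], list(beta0 = log(17), b = b,
    p = 8, gamma = 1), spec2)), 8, 1)
  expect_equal(m1 / m0, exp(0.1), tolerance = 1e-12)
})

test_that("penalised-complexity prior density has its closed form", {
  u <- 1; alpha <- 0.01
  theta <- -log(alpha) / u
  for (logtau in c(-1, 0, 2)) {
    sigma <- exp(-logtau / 2)
    pc <- afstrend:::pc_prior_logtau(logtau, u, alpha)
    expect_equal(exp(pc$value), theta * exp(-theta * sigma) * sigma / 2,
                 tolerance = 1e-12)
    h <- 1e-6
    num <- (afstrend:::pc_prior_logtau(logtau + h, u, alpha)$value -
              afstrend:::pc_prior_logtau(logtau - h, u, alpha)$value) / (2 * h)
    expect_equal(pc$grad, num, tolerance = 1e-6)
  }
  # at sigma = 1: density of sigma is theta * exp(-theta) = theta * alpha
  pc0 <- afstrend:::pc_prior_logtau(0, u, alpha)
  expect_equal(exp(pc0$value) / (1 / 2), theta * alpha, tolerance = 1e-12)
})

test_that("analytic gradient and Hessian agree with finite differences", {
  recs <- sim_fixture("decreasing", "typeI", 2)[1:600, ]
  for (label in c("M1", "M2", "M5")) {
    spec <- afs_spec_m(label)
    dat <- afstrend:::prepare_fit_data(recs, spec)
    layout <- afstrend:::param_layout(dat)
    set.seed(42)
    th <- afstrend:::default_start(dat, layout) +
      rnorm(layout$npar, 0, 0.05)
    lp <- afstrend:::logpost_core(th, dat, layout)
    gnum <- numeric(layout$npar)
    for (i in seq_len(layout$npar)) {
      h <- 1e-6 * max(1, abs(th[i]))
      tp <- th; tp[i] <- th[i] + h
      tm <- th; tm[i] <- th[i] - h
      gnum[i] <- (afstrend:::logpost_core(tp, dat, layout)$value -
                    afstrend:::logpost_core(tm, dat, layout)$value) / (2 * h)
    }
    expect_equal(lp$grad, gnum, tolerance = 1e-4)
    hi <- afstrend:::hess_inner(th, dat, layout)
    Hnum <- matrix(0, length(hi$inner), length(hi$inner))
    for (j in seq_along(hi$inner)) {
      i <- hi$inner[j]
      h <- 1e-5 * max(1, abs(th[i]))
      tp <- th; tp[i] <- th[i] + h
      tm <- th; tm[i] <- th[i] - h
      Hnum[, j] <- (afstrend:::logpost_core(tp, dat, layout)$grad[hi$inner] -
                      afstrend:::logpost_core(tm, dat, layout)$grad[hi$inner]) /
        (2 * h)
    }
    expect_lt(max(abs(-Hnum - hi$negH)) / max(1, max(abs(Hnum))), 1e-5)
  }
})

test_that("single-survey intercept fit agrees with an independent optimiser", {
  recs <- iid_lsl_records(200, seed = 3)
  spec <- afs_spec_m("M1")
  fit <- fit_afs(recs, spec, seed = 1)
  # independent route: direct Nelder-Mead on the same penalised objective
  # written from the public distribution functions
  obj <- function(par) {
    rate <- exp(-par[1]); p <- exp(par[2]); g <- exp(par[3])
    ev <- recs$ever_sex == 1
    a <- recs$reported_afs[ev]
    ll <- sum(log(plsl(a, rate, p, g, lower.tail = FALSE) -
                    plsl(a + 1, rate, p, g, lower.tail = FALSE))) +
      sum(log(plsl(recs$age_at_report[!ev], rate, p, g,
                   lower.tail = FALSE)))
    -(ll - 0.5 * sum(par^2))
  }
  ref <- optim(c(log(17), log(6), log(0.5)), obj,
               control = list(maxit = 5000, reltol = 1e-14))
  med_ref <- lsl_median(exp(-ref$par[1]), exp(ref$par[2]), exp(ref$par[3]))
  med_fit <- lsl_median(exp(-fit$params$beta0), fit$params$p,
                        fit$params$gamma)
  expect_equal(med_fit, med_ref, tolerance = 1e-4)
})
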