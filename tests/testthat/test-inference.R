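# Fitting, the Gaussian approximation, and derived quantities.

test_that("intercept-only fit recovers the generating median", {
  recs <- iid_lsl_records(5000, rate = lsl_rate_for_median(17, 8, 0.6),
                          shape = 8, skew = 0.6, seed = 1)
  fit <- fit_afs(recs, afs_spec_m("M1"), seed = 1)
  expect_true(fit$converged)
  med <- lsl_median(exp(-fit$params$beta0), fit$params$p, fit$params$gamma)
  expect_lt(abs(med - 17), 0.15)
})

test_that("null data yield a near-zero RW1 cohort effect", {
  for (seed in c(301, 302)) {
    recs <- sim_fixture("constant", "none", 3, seed = seed,
                        sample_per_survey = 3334)
    fit <- fit_afs(recs, afs_spec_m("M3"), seed = 1, n_starts = 1,
                   hessian = FALSE)
    expect_true(fit$converged)
    expect_lt(max(abs(fit$params$f)), 0.05)
  }
})

test_that("the fitted mode is invariant to record order", {
  recs <- sim_fixture("decreasing", "none", 2)
  fit1 <- fit_afs(recs, afs_spec_m("M3"), seed = 1, n_starts = 1,
                  hessian = FALSE)
  set.seed(8)
  fit2 <- fit_afs(recs[sample(nrow(recs)), ], afs_spec_m("M3"), seed = 1,
                  n_starts = 1, hessian = FALSE)
  expect_equal(fit1$mode, fit2$mode, tolerance = 1e-8)
})

test_that("posterior draws reproduce the stored Gaussian approximation", {
  recs <- sim_fixture("decreasing", "none", 2)
  fit <- fit_afs(recs, afs_spec_m("M2"), seed = 1, n_starts = 1)
  expect_error(posterior_draws(fit, 1), "at least 2")
  dr <- posterior_draws(fit, 1e5, seed = 4)
  inner <- afstrend:::hess_inner(fit$mode,
    afstrend:::prepare_fit_data(recs, fit$spec), fit$layout)$inner
  mu <- colMeans(dr)
  se <- sqrt(diag(fit$covariance)) / sqrt(nrow(dr))
  expect_true(all(abs(mu - fit$mode)[inner] < 3 * pmax(se[inner], 1e-12)))
  emp <- cov(dr[, inner])
  ref <- fit$covariance[inner, inner]
  expect_lt(norm(emp - ref, "F") / norm(ref, "F"), 0.05)
})

test_that("every draw honours the sum-to-zero constraints", {
  recs <- sim_fixture("decreasing", "typeI", 3)
  fit <- fit_afs(recs, afs_spec_m("M5"), seed = 1, n_starts = 1)
  dr <- posterior_draws(fit, 50, seed = 9)
  for (i in c(1, 25, 50)) {
    pp <- afstrend:::expand_draw(dr[i, ], fit)
    expect_equal(sum(pp$f), 0, tolerance = 1e-10)
    expect_equal(sum(pp$b), 0, tolerance = 1e-10)
  }
})

test_that("cohort medians follow the closed form and recover truth", {
  recs <- sim_fixture("decreasing", "typeI", 3)
  fit <- fit_afs(recs, afs_spec_m("M5"), seed = 1, n_starts = 1)
  med <- median_afs_by_cohort(fit)
  # reconstruct by hand from the parameter list
  pp <- fit$params
  bref <- pp$b[match(fit$spec$reference_age, fit$ages)]
  byhand <- exp(pp$beta0 + pp$f + bref) *
    (2^(1 / pp$gamma) - 1)^(-1 / pp$p)
  expect_equal(med$median, byhand, tolerance = 1e-12)
  # skew = 1 reduction: median = exp(eta)
  expect_equal(lsl_median(exp(-1.1), 4, 1), exp(1.1), tolerance = 1e-12)
  # a +0.06 shift in f multiplies the median by exp(0.06)
  i <- 10
  expect_equal(byhand[i] * exp(0.06),
               exp(pp$beta0 + pp$f[i] + 0.06 + bref) *
                 (2^(1 / pp$gamma) - 1)^(-1 / pp$p), tolerance = 1e-12)
  # recovery: cohorts with plenty of observations within half a year
  sc <- afs_scenario(trend = "decreasing", bias_type = "typeI",
                     n_surveys = 3, sample_per_survey = 3000L)
  recs_big <- sim_fixture("decreasing", "typeI", 3, seed = 12,
                          sample_per_survey = 3000L)
  fit_big <- fit_afs(recs_big, afs_spec_m("M5"), seed = 1, n_starts = 1,
                     hessian = FALSE)
  med_big <- median_afs_by_cohort(fit_big)
  heavy <- as.integer(names(which(table(recs_big$birth_year) >= 200)))
  expect_gt(length(heavy), 5)
  for (cy in heavy[seq(1, length(heavy), by = 4)]) {
    expect_lt(abs(med_big$median[match(cy, med_big$birth_year)] -
                    true_median_for_cohort(cy, sc)), 0.5)
  }
})

test_that("bias curve is anchored at the reference age", {
  recs <- sim_fixture("decreasing", "typeI", 3)
  fit <- fit_afs(recs, afs_spec_m("M5"), seed = 1, n_starts = 1)
  dr <- posterior_draws(fit, 200, seed = 2)
  bc <- bias_curve(fit, dr)
  expect_equal(bc$effect[bc$age == 23], 0)
  expect_true(all(bc$lower <= bc$effect & bc$effect <= bc$upper))
  # no age effect: empty curve
  fit3 <- fit_afs(recs, afs_spec_m("M3"), seed = 1, n_starts = 1,
                  hessian = FALSE)
  expect_equal(nrow(bias_curve(fit3)), 0)
})

test_that("re-centring leaves derived medians unchanged", {
  # shifting level from b to beta0 is absorbed: medians computed with the
  # re-centred curve match medians computed from the raw sum-to-zero b
  recs <- sim_fixture("decreasing", "typeI", 3)
  fit <- fit_afs(recs, afs_spec_m("M5"), seed = 1, n_starts = 1,
                 hessian = FALSE)
  pp <- fit$params
  bref <- pp$b[match(23L, fit$ages)]
  med_recentred <- exp((pp$beta0 + bref) + pp$f + 0) *
    (2^(1 / pp$gamma) - 1)^(-1 / pp$p)
  expect_equal(median_afs_by_cohort(fit)$median, med_recentred,
               tolerance = 1e-12)
})

test_that("predicted proportions before a cutoff age behave as contracted", {
  recs <- sim_fixture("constant", "none", 3)
  fit5 <- fit_afs(recs, afs_spec_m("M5"), seed = 1, n_starts = 1,
                  hessian = FALSE)
  fit3 <- fit_afs(recs, afs_spec_m("M3"), seed = 1, n_starts = 1,
                  hessian = FALSE)
  # far above the support the proportion is ~1 (age_range extended so the
  # evaluation grid covers the cutoff)
  pr60 <- predicted_prop_before_age(fit5, recs, cutoff_age = 45L)
  expect_true(all(pr60$prop > 0.97))
  # on unbiased data, M3 and M5 predictions agree within Monte-Carlo error
  p5 <- predicted_prop_before_age(fit5, recs, cutoff_age = 18L)
  p3 <- predicted_prop_before_age(fit3, recs, cutoff_age = 18L)
  m <- merge(p5, p3, by = c("survey_id", "cohort_group"))
  expect_lt(max(abs(m$prop.x - m$prop.y)), 0.06)
  # M5 predictions differ across surveys for a fixed cohort group when the
  # age effect is non-zero (same cohort reported at different ages)
  recsI <- sim_fixture("constant", "typeI", 3)
  fitI <- fit_afs(recsI, afs_spec_m("M5"), seed = 1, n_starts = 1,
                  hessian = FALSE)
  pI <- predicted_prop_before_age(fitI, recsI, cutoff_age = 18L)
  spread <- tapply(pI$prop, pI$cohort_group, function(x) diff(range(x)))
  expect_gt(max(spread, na.rm = TRUE), 0.01)
})
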