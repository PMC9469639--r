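# Log-skew-logistic core and the comparator families.

test_that("survival function: closed forms, limits and monotonicity", {
  # (rate*t)^(-p) = 1 at t = 1/rate, so with skew = 1, F = 1/2
  for (p in c(0.5, 2, 8))
    expect_equal(plsl(17, rate = 1 / 17, shape = p, skew = 1,
                      lower.tail = FALSE), 0.5)
  # independent bisection oracle for S(t) = 0.5 at (0.05, 8, 0.5)
  root <- uniroot(function(t)
    plsl(t, 0.05, 8, 0.5, lower.tail = FALSE) - 0.5,
    c(1, 100), tol = 1e-12)$root
  expect_equal(root, 17.434, tolerance = 1e-3)
  # limits
  expect_equal(plsl(1e-8, 0.06, 6, 0.4, lower.tail = FALSE), 1)
  expect_equal(plsl(1e8, 0.06, 6, 0.4, lower.tail = FALSE), 0)
  tg <- seq(1, 60, by = 0.5)
  S <- plsl(tg, 0.06, 6, 0.4, lower.tail = FALSE)
  expect_true(all(diff(S) <= 0))
  expect_equal(S + plsl(tg, 0.06, 6, 0.4), rep(1, length(tg)))
})

test_that("density: point value, derivative of survival, and total mass", {
  expect_equal(dlsl(1, 1, 1, 1), 0.25)
  # finite-difference oracle: f = -dS/dt
  h <- 1e-5
  for (t in c(12, 16, 25)) {
    fd <- -(plsl(t + h, 0.05, 8, 0.5, lower.tail = FALSE) -
              plsl(t - h, 0.05, 8, 0.5, lower.tail = FALSE)) / (2 * h)
    expect_equal(dlsl(t, 0.05, 8, 0.5), fd, tolerance = 1e-6)
  }
  expect_equal(
    integrate(dlsl, 0, 200, rate = 0.06, shape = 6, skew = 0.4,
              rel.tol = 1e-9)$value,
    1, tolerance = 1e-6)
})

test_that("hazard is f/S and matches -d log S/dt", {
  expect_equal(lsl_hazard(1, 1, 1, 1), 0.5)
  tg <- 5:40
  expect_equal(lsl_hazard(tg, 0.05, 8, 0.5) *
                 plsl(tg, 0.05, 8, 0.5, lower.tail = FALSE),
               dlsl(tg, 0.05, 8, 0.5), tolerance = 1e-12)
  h <- 1e-5
  fd <- -(log(plsl(18 + h, 0.05, 8, 0.5, lower.tail = FALSE)) -
            log(plsl(18 - h, 0.05, 8, 0.5, lower.tail = FALSE))) / (2 * h)
  expect_equal(lsl_hazard(18, 0.05, 8, 0.5), fd, tolerance = 1e-6)
  # non-monotone for AFS-like parameters: rises then declines
  hz <- lsl_hazard(seq(10, 45), 1 / 17, 8, 0.6)
  expect_gt(which.max(hz), 1)
  expect_lt(which.max(hz), length(hz))
})

test_that("quantiles invert the CDF and reproduce the median formula", {
  expect_equal(qlsl(0.5, 1 / 17, 5, 1), 17)
  # bisection oracle
  root <- uniroot(function(t) plsl(t, 0.05, 8, 0.5) - 0.5,
                  c(1, 100), tol = 1e-12)$root
  expect_equal(qlsl(0.5, 0.05, 8, 0.5), root, tolerance = 1e-8)
  expect_equal(qlsl(0.5, 0.05, 8, 0.5), 20 * 3^(-1 / 8), tolerance = 1e-10)
  tg <- seq(5, 40, by = 2.5)
  expect_equal(qlsl(plsl(tg, 0.07, 7, 0.8), 0.07, 7, 0.8), tg,
               tolerance = 1e-8)
  # median closed form vs numeric inversion over a parameter grid
  for (rate in c(0.04, 1 / 17, 0.08))
    for (shape in c(3, 8))
      for (skew in c(0.4, 1, 2.5)) {
        byroot <- uniroot(function(t) plsl(t, rate, shape, skew) - 0.5,
                          c(0.1, 500), tol = 1e-13)$root
        expect_equal(lsl_median(rate, shape, skew), byroot,
                     tolerance = 1e-8)
        expect_equal(lsl_rate_for_median(byroot, shape, skew), rate,
                     tolerance = 1e-8)
      }
})

test_that("random generation is reproducible and matches the analytic law", {
  set.seed(7); x1 <- rlsl(1000, 0.06, 6, 0.4)
  set.seed(7); x2 <- rlsl(1000, 0.06, 6, 0.4)
  expect_identical(x1, x2)
  set.seed(11)
  x <- rlsl(1e5, 0.06, 6, 0.4)
  ks <- suppressWarnings(
    ks.test(x, function(q) plsl(q, 0.06, 6, 0.4)))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(median(x) - qlsl(0.5, 0.06, 6, 0.4)), 0.1)
})

test_that("skew = 1 collapses every function to the log-logistic", {
  tg <- seq(2, 60, by = 0.5)
  ll_S <- 1 - 1 / (1 + (0.06 * tg)^(-7))^1  # direct two-parameter form
  expect_equal(plsl(tg, 0.06, 7, 1, lower.tail = FALSE), ll_S,
               tolerance = 1e-12)
  expect_equal(dist_survival("loglogistic", c(0.06, 7), tg),
               dist_survival("logskewlogistic", c(0.06, 7, 1), tg),
               tolerance = 1e-12)
})

test_that("family dispatch and special cases", {
  expect_equal(dist_survival("lognormal", c(log(17), 0.3), 17), 0.5)
  # gamma(shape k, rate r) as the sigma = Q = 1/sqrt(k) generalised gamma
  k <- 4; r <- 0.25
  tg <- seq(2, 80, by = 2)
  expect_equal(
    dist_survival("gengamma", c(log(k / r), 1 / sqrt(k), 1 / sqrt(k)), tg),
    dist_survival("gamma", c(k, r), tg), tolerance = 1e-10)
  expect_error(dist_survival("weibull", c(1, 2), 10), "unknown")
  expect_error(dist_survival("gamma", c(1, 2, 3), 10), "parameters")
})

test_that("invalid arguments raise domain errors", {
  expect_error(plsl(10, rate = -1, shape = 2, skew = 1), "positive")
  expect_error(dlsl(-3, 1, 1, 1), "positive")
  expect_error(qlsl(1.2, 1, 1, 1), "in \\(0, 1\\)")
  expect_error(qlsl(0, 1, 1, 1))
})
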