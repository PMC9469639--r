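# Empirical-Bayes fitting of the AFS model: joint MAP over the intercept,
# latent effects, log-precisions and log shape/skewness, with a Gaussian
# (Laplace) approximation at the mode for posterior uncertainty.

default_start <- function(dat, layout) {
  theta <- numeric(layout$npar)
  ev <- dat$event
  med0 <- if (any(ev)) stats::median(exp(dat$l1[ev])) else 17
  theta[layout$beta0] <- log(max(med0, 10))
  if (!is.null(layout$logtau_f)) theta[layout$logtau_f] <- log(400)
  if (!is.null(layout$logtau_b)) theta[layout$logtau_b] <- log(400)
  theta[layout$logp] <- log(6)
  if (!is.null(layout$loggamma)) theta[layout$loggamma] <- log(0.5)
  theta
}

#' Fit an AFS model by empirical-Bayes penalised likelihood
#'
#' The "inner" parameters (intercept, effect coefficients, log shape, log
#' skewness) are estimated by maximising the penalised log-likelihood at
#' fixed RW1 precisions, with BFGS and analytic gradients. The RW1
#' log-precisions are hyperparameters, estimated by maximising the
#' Laplace-approximated marginal posterior: the inner parameters are
#' integrated out with a Gaussian approximation at their conditional mode,
#' using the analytic inner Hessian. (A joint mode over effects and
#' precisions does not exist — the joint posterior density is unbounded
#' along effects -> 0, precision -> infinity — so the marginal step is
#' essential, not a refinement.) RW1 effects are parameterised by their
#' first differences, making the sum-to-zero constraints exact by
#' construction. Multiple jittered starts (seeded) guard against bad local
#' optima.
#'
#' @param records record data frame (see [validate_records()]).
#' @param spec an [afs_spec()].
#' @param seed integer seed controlling the start jitter.
#' @param n_starts number of jittered inner starts (default 3).
#' @param hessian keep the Laplace covariance at the mode (default TRUE;
#'   skipping it saves a little time when only point estimates are needed,
#'   e.g. inside large simulation studies).
#' @param maxit maximum BFGS iterations per inner solve.
#' @return an object of class `afs_fit` with elements `spec`, `mode` (free
#'   parameter vector), `params` (natural-scale list: `beta0`, `f`, `b`,
#'   `p`, `gamma`, precisions), `covariance` (over the free vector;
#'   hyperparameter rows are zero — draws condition on the estimated
#'   precisions), `converged`, `n_obs`, `log_posterior` (Laplace marginal
#'   criterion at the optimum), `cohorts`, `ages`.
#' @export
fit_afs <- function(records, spec = afs_spec_m("M5"), seed = 1L,
                    n_starts = 3L, hessian = TRUE, maxit = 60L) {
  dat <- prepare_fit_data(records, spec)
  if (spec$cohort_effect != "none" && length(unique(dat$cohort_idx)) < 2)
    stop("cohort effects need records from at least 2 distinct cohorts",
         call. = FALSE)
  layout <- param_layout(dat)
  outer_idx <- c(layout$logtau_f, layout$logtau_b)
  inner_idx <- setdiff(seq_len(layout$npar), outer_idx)

  theta_full <- function(x, psi) {
    th <- numeric(layout$npar)
    th[inner_idx] <- x
    if (length(outer_idx)) th[outer_idx] <- psi
    th
  }
  # damped Newton with Armijo backtracking on the penalised objective;
  # returns the conditional mode, its objective and the negative Hessian
  # there (reused for the Laplace log-determinant and the covariance)
  solve_inner <- function(psi, x0) {
    x <- x0
    lp <- logpost_core(theta_full(x, psi), dat, layout)
    if (!is.finite(lp$value)) stop("non-finite objective at start")
    v <- lp$value
    g <- lp$grad[inner_idx]
    nh <- NULL
    for (it in seq_len(maxit)) {
      nh <- hess_inner(theta_full(x, psi), dat, layout)$negH
      lam <- 0
      repeat {
        ch <- tryCatch(chol(nh + diag(lam, nrow(nh))), error = function(e) NULL)
        if (!is.null(ch)) break
        lam <- if (lam == 0) 1e-4 else lam * 10
        if (lam > 1e8) stop("inner Hessian irreparably indefinite")
      }
      d <- backsolve(ch, backsolve(ch, g, transpose = TRUE))
      gd <- sum(g * d)
      step <- 1
      repeat {
        xn <- x + step * d
        lpn <- logpost_core(theta_full(xn, psi), dat, layout)
        if (is.finite(lpn$value) && lpn$value >= v + 1e-4 * step * gd) break
        step <- step / 2
        if (step < 1e-12) break
      }
      if (step < 1e-12) break
      x <- xn; v <- lpn$value; g <- lpn$grad[inner_idx]
      if (max(abs(g)) <= 1e-8 * max(1, abs(v))) break
    }
    nh <- hess_inner(theta_full(x, psi), dat, layout)$negH
    list(par = x, value = -v, negH = nh)
  }
  # negative log Laplace marginal posterior of the log-precisions
  warm <- NULL
  laplace_neg <- function(psi) {
    opt <- solve_inner(psi, warm)
    warm <<- opt$par
    ld <- determinant(opt$negH, logarithm = TRUE)$modulus
    -(-opt$value - 0.5 * as.numeric(ld) +
        0.5 * length(inner_idx) * log(2 * pi))
  }

  set.seed(as.integer(seed) %% .Machine$integer.max)
  psi0 <- rep(log(400), length(outer_idx))   # sigma ~ 0.05 to start
  x0 <- default_start(dat, layout)[inner_idx]
  best <- NULL
  jit <- match(c(layout$beta0, layout$logp, layout$loggamma), inner_idx)
  for (s in seq_len(n_starts)) {
    x <- x0
    if (s > 1) x[jit] <- x[jit] + stats::rnorm(length(jit), 0, 0.15)
    opt <- solve_inner(psi0, x)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  warm <- best$par

  if (length(outer_idx)) {
    oo <- stats::optim(psi0, laplace_neg, method = "Nelder-Mead",
                       control = list(maxit = 60, reltol = 1e-5,
                                      warn.1d.NelderMead = FALSE))
    psi_hat <- pmin(pmax(oo$par, -6), 16)
    marg <- -oo$value
  } else {
    psi_hat <- numeric(0)
    marg <- -best$value   # no hyperparameters: plain penalised likelihood
  }
  final <- solve_inner(psi_hat, warm)
  mode <- theta_full(final$par, psi_hat)

  g_mode <- logpost_core(mode, dat, layout)$grad
  relg <- max(abs(g_mode[inner_idx])) / max(1, abs(final$value))
  converged <- is.finite(relg) && relg < 1e-5

  covariance <- NULL
  if (hessian) {
    nh <- final$negH
    cov_in <- safe_inverse((nh + t(nh)) / 2)
    covariance <- matrix(0, layout$npar, layout$npar)
    covariance[inner_idx, inner_idx] <- cov_in
  }
  pp <- unpack_params(mode, dat, layout)
  structure(list(
    spec = spec, mode = mode, layout = layout,
    params = list(beta0 = pp$beta0, f = pp$f, b = pp$b, p = pp$p,
                  gamma = pp$gamma,
                  tau_f = if (!is.null(pp$logtau_f)) exp(pp$logtau_f),
                  tau_b = if (!is.null(pp$logtau_b)) exp(pp$logtau_b)),
    covariance = covariance, converged = converged,
    grad_norm = relg, n_obs = dat$n_obs,
    log_posterior = marg,
    cohorts = dat$cohorts, ages = dat$ages,
    cohort_centered = dat$cohort_centered, age_centered = dat$age_centered
  ), class = "afs_fit")
}

#' @export
print.afs_fit <- function(x, ...) {
  cat("AFS model fit (", x$spec$distribution, ", cohort: ",
      x$spec$cohort_effect, ", age: ", x$spec$age_effect, ")\n", sep = "")
  cat("  n =", x$n_obs, "| log-posterior =", format(x$log_posterior),
      "| converged:", x$converged, "\n")
  cat("  shape p =", format(x$params$p, digits = 4),
      "| skewness gamma =", format(x$params$gamma, digits = 4), "\n")
  m <- exp(x$params$beta0) * (2^(1 / x$params$gamma) - 1)^(-1 / x$params$p)
  cat("  baseline median AFS =", format(m, digits = 4), "years\n")
  invisible(x)
}

# Jacobian of a gradient function by central differences (gives the Hessian)
grad_jacobian <- function(gfun, x, h = 1e-4) {
  d <- length(x)
  J <- matrix(0, d, d)
  for (i in seq_len(d)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    J[, i] <- (gfun(xp) - gfun(xm)) / (2 * hi)
  }
  J
}

# Inverse of a (near) positive-definite matrix; eigenvalue clamping gives a
# pseudo-inverse when the curvature is singular (e.g. a precision at its
# bound), with a warning.
safe_inverse <- function(H) {
  ee <- eigen(H, symmetric = TRUE)
  lam <- ee$values
  tol <- max(abs(lam)) * 1e-10
  if (any(lam < tol)) {
    warning("singular or indefinite curvature at mode; using pseudo-inverse")
    lam <- pmax(lam, tol)
  }
  V <- ee$vectors
  V %*% (t(V) / lam)
}

#' Draw parameters from the Gaussian approximation at the mode
#'
#' Multivariate normal draws with the Laplace covariance; RW1 effects are
#' reconstructed from the drawn increments, so every draw satisfies the
#' sum-to-zero constraints exactly.
#'
#' @param fitted an [fit_afs()] result with a covariance.
#' @param n_draws number of draws (>= 2).
#' @param seed integer seed.
#' @return matrix `n_draws x npar` of free-parameter draws, with the layout
#'   attached as attribute `layout`.
#' @export
posterior_draws <- function(fitted, n_draws = 1000L, seed = 1L) {
  if (n_draws < 2) stop("need at least 2 draws", call. = FALSE)
  if (is.null(fitted$covariance))
    stop("fit has no covariance; rerun fit_afs(hessian = TRUE)", call. = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  S <- (fitted$covariance + t(fitted$covariance)) / 2
  ee <- eigen(S, symmetric = TRUE)
  L <- ee$vectors %*% diag(sqrt(pmax(ee$values, 0)), nrow = length(ee$values))
  Z <- matrix(stats::rnorm(n_draws * length(fitted$mode)), nrow = n_draws)
  draws <- Z %*% t(L)
  draws <- sweep(draws, 2, fitted$mode, "+")
  attr(draws, "layout") <- fitted$layout
  draws
}

# expand one free-parameter draw into (beta0, f, b, p, gamma)
expand_draw <- function(theta, fitted) {
  layout <- fitted$layout
  spec <- fitted$spec
  f <- switch(spec$cohort_effect,
    none = rep(0, length(fitted$cohorts)),
    linear = theta[layout$f] * fitted$cohort_centered,
    rw1 = rw1_expand(theta[layout$f]))
  b <- switch(spec$age_effect,
    none = rep(0, length(fitted$ages)),
    linear = theta[layout$b] * fitted$age_centered,
    rw1 = rw1_expand(theta[layout$b]))
  list(beta0 = theta[layout$beta0], f = f, b = b,
       p = exp(theta[layout$logp]),
       gamma = if (!is.null(layout$loggamma)) exp(theta[layout$loggamma]) else 1)
}

# bias-term value at the reference age (0 when there is no age effect)
b_at_reference <- function(b, ages, reference_age) {
  if (!length(b) || all(b == 0)) return(0)
  i <- match(reference_age, ages)
  if (is.na(i))
    stop("reference age ", reference_age, " outside fitted age range",
         call. = FALSE)
  b[i]
}

median_from_draw <- function(pp, fitted) {
  bref <- b_at_reference(pp$b, fitted$ages, fitted$spec$reference_age)
  exp(pp$beta0 + pp$f + bref) * (2^(1 / pp$gamma) - 1)^(-1 / pp$p)
}

#' Cohort trajectories of median AFS
#'
#' For each birth year in the fitted range, the model median AFS
#' \eqn{\exp(\beta_0 + f(\mathrm{bch}) + b(\mathrm{ref}))\,
#' (2^{1/\gamma} - 1)^{-1/p}}, i.e. with the age-at-report bias term fixed at
#' the reference age (where it is assumed zero after re-centring). Point
#' estimate at the mode; equal-tailed 95% intervals from draws if supplied.
#'
#' @param fitted an [fit_afs()] result.
#' @param draws optional matrix from [posterior_draws()].
#' @return data frame with columns `birth_year`, `median`, and with draws
#'   `lower`, `upper`.
#' @export
median_afs_by_cohort <- function(fitted, draws = NULL) {
  pp <- expand_draw(fitted$mode, fitted)
  est <- median_from_draw(pp, fitted)
  out <- data.frame(birth_year = fitted$cohorts, median = est)
  if (!is.null(draws)) {
    M <- apply(draws, 1, function(th)
      median_from_draw(expand_draw(th, fitted), fitted))
    qs <- apply(M, 1, stats::quantile, probs = c(0.025, 0.975))
    out$lower <- qs[1, ]
    out$upper <- qs[2, ]
  }
  out
}

#' Age-at-report bias curve
#'
#' The fitted bias term re-centred at the reference age,
#' \eqn{b(\mathrm{age}) - b(\mathrm{ref})}, so the curve is exactly zero
#' there; the offset is simultaneously absorbed into the intercept in all
#' derived quantities (the likelihood is invariant to this shift). Empty for
#' models without an age effect.
#'
#' @inheritParams median_afs_by_cohort
#' @return data frame with columns `age`, `effect` and, with draws,
#'   `lower`, `upper`.
#' @export
bias_curve <- function(fitted, draws = NULL) {
  if (fitted$spec$age_effect == "none")
    return(data.frame(age = integer(0), effect = numeric(0)))
  pp <- expand_draw(fitted$mode, fitted)
  bref <- b_at_reference(pp$b, fitted$ages, fitted$spec$reference_age)
  out <- data.frame(age = fitted$ages, effect = pp$b - bref)
  if (!is.null(draws)) {
    B <- apply(draws, 1, function(th) {
      pd <- expand_draw(th, fitted)
      pd$b - b_at_reference(pd$b, fitted$ages, fitted$spec$reference_age)
    })
    qs <- apply(B, 1, stats::quantile, probs = c(0.025, 0.975))
    out$lower <- qs[1, ]
    out$upper <- qs[2, ]
  }
  out
}

#' Model-implied proportion with sexual debut before a cutoff age
#'
#' For each record, \eqn{P(\mathrm{AFS} < c) = 1 - S(c)} evaluated at the
#' record's own cohort and report age, then aggregated with the scaled
#' weights by survey and cohort group — directly comparable with the
#' descriptive [prop_before_age()]. Only respondents aged at least the
#' cutoff at interview are included.
#'
#' @param fitted an [fit_afs()] result.
#' @param records the record data frame to predict for.
#' @param cutoff_age cutoff age in years (default 18).
#' @param cohort_bins integer vector of bin breakpoints for birth years
#'   (default 5-year bins over the fitted range).
#' @return data frame with `survey_id`, `cohort_group`, `prop`.
#' @export
predicted_prop_before_age <- function(fitted, records, cutoff_age = 18L,
                                      cohort_bins = NULL) {
  records <- validate_records(records)
  records <- scale_weights(records)
  pp <- expand_draw(fitted$mode, fitted)
  bch <- pmin(pmax(records$birth_year, min(fitted$cohorts)), max(fitted$cohorts))
  aar <- pmin(pmax(records$age_at_report, min(fitted$ages)), max(fitted$ages))
  eta <- pp$beta0 + pp$f[match(bch, fitted$cohorts)] +
    pp$b[match(aar, fitted$ages)]
  pr <- exp(-pp$gamma * .log1pexp(pp$p * (eta - log(cutoff_age))))
  keep <- records$age_at_report >= cutoff_age
  if (is.null(cohort_bins)) {
    lo <- floor(min(records$birth_year) / 5) * 5
    hi <- ceiling((max(records$birth_year) + 1) / 5) * 5
    cohort_bins <- seq(lo, hi, by = 5)
  }
  grp <- cut(records$birth_year, breaks = cohort_bins, right = FALSE,
             dig.lab = 8)
  df <- data.frame(survey_id = as.character(records$survey_id),
                   cohort_group = as.character(grp),
                   w = records$scaled_weight, pr = pr)[keep, ]
  agg <- stats::aggregate(cbind(wpr = w * pr, w = w) ~ survey_id + cohort_group,
                          data = df, FUN = sum)
  data.frame(survey_id = agg$survey_id, cohort_group = agg$cohort_group,
             prop = agg$wpr / agg$w)
}
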