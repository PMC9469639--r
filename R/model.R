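# Survey-weighted, interval-censored pseudo-likelihood for AFS.
#
# Each record contributes, with its Kish-scaled weight w* as an exponent on
# the likelihood (i.e. multiplicatively on the log-likelihood):
#   event (ever_sex = 1, reported AFS = a):  w* log[S(a) - S(a + 1)]
#   censored (ever_sex = 0, interviewed at age a):  w* log S(a)
# where S is log-skew-logistic with record-specific rate
#   lambda_i = exp(-eta_i),  eta_i = beta0 + f(birth_year_i) + b(age_i),
# and shared shape p and skewness gamma. f is the birth-cohort trend, b the
# age-at-report bias term; each may be absent, linear, or a first-order
# random walk (RW1) with sum-to-zero constraint and a penalised-complexity
# prior on its precision.

REQUIRED_COLS <- c("survey_id", "survey_year", "birth_year", "age_at_report",
                   "ever_sex", "reported_afs", "design_weight")

#' Validate a data frame of survey records
#'
#' Checks the fixed schema (`survey_id`, `survey_year`, `birth_year`,
#' `age_at_report`, `ever_sex`, `reported_afs`, `design_weight`), drops rows
#' reporting ever having had sex but with unknown AFS, and enforces basic
#' consistency: positive design weights, `age_at_report` within one year of
#' `survey_year - birth_year` (interview-timing tolerance), and reported AFS
#' not exceeding age at report.
#'
#' @param records data frame with the schema above.
#' @return the validated data frame, with an attribute `n_dropped_unknown`
#'   counting rows dropped for unknown AFS.
#' @export
validate_records <- function(records) {
  miss <- setdiff(REQUIRED_COLS, names(records))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  records$ever_sex <- as.integer(records$ever_sex)
  if (!all(records$ever_sex %in% c(0L, 1L)))
    stop("'ever_sex' must be 0/1", call. = FALSE)
  int_cols <- c("survey_year", "birth_year", "age_at_report")
  for (cc in int_cols) {
    v <- records[[cc]]
    if (any(!is.finite(v)) || any(v != round(v)))
      stop("column '", cc, "' must be integer-valued", call. = FALSE)
  }
  # respondents with unknown AFS are dropped, counted
  unknown <- records$ever_sex == 1L & !is.finite(records$reported_afs)
  n_drop <- sum(unknown)
  if (n_drop > 0) records <- records[!unknown, , drop = FALSE]
  if (any(records$design_weight <= 0) || any(!is.finite(records$design_weight)))
    stop("'design_weight' must be positive", call. = FALSE)
  gap <- abs(records$age_at_report - (records$survey_year - records$birth_year))
  if (any(gap > 1))
    stop("age_at_report inconsistent with survey_year - birth_year (>1 year)",
         call. = FALSE)
  ev <- records$ever_sex == 1L
  if (any(records$reported_afs[ev] > records$age_at_report[ev]))
    stop("reported_afs exceeds age_at_report", call. = FALSE)
  if (any(ev & records$reported_afs < 0))
    stop("negative reported_afs", call. = FALSE)
  attr(records, "n_dropped_unknown") <- n_drop
  records
}

#' Kish effective sample size
#'
#' \eqn{n_{\mathrm{eff}} = (\sum_i w_i)^2 / \sum_i w_i^2}: the equal-weight
#' sample size carrying the same information as the weighted sample. Equals
#' n when all weights are equal, and is otherwise strictly smaller.
#'
#' @param weights positive design weights.
#' @export
kish_neff <- function(weights) {
  if (length(weights) == 0) stop("empty weight vector", call. = FALSE)
  if (any(weights <= 0) || any(!is.finite(weights)))
    stop("weights must be positive", call. = FALSE)
  sum(weights)^2 / sum(weights^2)
}

#' Scale design weights to the Kish effective sample size
#'
#' Within each survey, raw weights are rescaled as
#' \eqn{w^*_{ik} = w_{ik} \, n_{\mathrm{eff},k} / \sum_i w_{ik}} so that they
#' sum to the survey's Kish effective sample size. Relative weights within a
#' survey are preserved, and multiplying all raw weights of a survey by any
#' constant leaves the scaled weights unchanged.
#'
#' @param records validated record data frame.
#' @return the data frame with an extra numeric column `scaled_weight`.
#' @export
scale_weights <- function(records) {
  w <- records$design_weight
  sid <- as.character(records$survey_id)
  ws <- numeric(length(w))
  for (s in unique(sid)) {
    idx <- sid == s
    ws[idx] <- w[idx] * kish_neff(w[idx]) / sum(w[idx])
  }
  records$scaled_weight <- ws
  records
}

#' Project a coefficient vector onto the sum-to-zero subspace
#'
#' Subtracts the mean; idempotent.
#'
#' @param coeffs numeric vector.
#' @export
project_sum_to_zero <- function(coeffs) {
  if (length(coeffs) == 0) stop("empty coefficient vector", call. = FALSE)
  coeffs - mean(coeffs)
}

#' Model specification
#'
#' Describes the distribution and effect structure of an AFS model. The five
#' standard structures are `M1` (intercept only), `M2` (+ linear birth-cohort
#' effect), `M3` (+ RW1 birth-cohort effect), `M4` (M3 + linear age-at-report
#' effect) and `M5` (M3 + RW1 age-at-report effect).
#'
#' @param distribution `"logskewlogistic"` (default) or `"loglogistic"`
#'   (skewness fixed at 1).
#' @param cohort_effect one of `"none"`, `"linear"`, `"rw1"`.
#' @param age_effect one of `"none"`, `"linear"`, `"rw1"`.
#' @param reference_age report age at which reporting is assumed unbiased;
#'   the fitted bias curve is re-centred to zero there (default 23).
#' @param pc_prior_u,pc_prior_alpha penalised-complexity prior for each RW1
#'   precision \eqn{\tau}: an exponential prior on \eqn{\sigma = \tau^{-1/2}}
#'   with \eqn{P(\sigma > u) = \alpha}; defaults u = 1, alpha = 0.01.
#' @param cohort_range,age_range optional integer `c(min, max)` ranges of
#'   birth years / report ages spanned by the latent effects; default is the
#'   observed range of the data at fitting time.
#' @return an object of class `afs_spec`.
#' @export
afs_spec <- function(distribution = "logskewlogistic",
                     cohort_effect = c("none", "linear", "rw1"),
                     age_effect = c("none", "linear", "rw1"),
                     reference_age = 23L,
                     pc_prior_u = 1, pc_prior_alpha = 0.01,
                     cohort_range = NULL, age_range = NULL) {
  distribution <- match.arg(distribution, c("logskewlogistic", "loglogistic"))
  cohort_effect <- match.arg(cohort_effect)
  age_effect <- match.arg(age_effect)
  stopifnot(pc_prior_u > 0, pc_prior_alpha > 0, pc_prior_alpha < 1)
  structure(list(distribution = distribution,
                 cohort_effect = cohort_effect,
                 age_effect = age_effect,
                 reference_age = as.integer(reference_age),
                 pc_prior_u = pc_prior_u,
                 pc_prior_alpha = pc_prior_alpha,
                 cohort_range = cohort_range,
                 age_range = age_range),
            class = "afs_spec")
}

#' Shorthand for the five standard model structures
#'
#' @param label one of `"M1"` ... `"M5"`.
#' @param ... further arguments passed to [afs_spec()].
#' @export
afs_spec_m <- function(label, ...) {
  eff <- switch(label,
    M1 = c("none", "none"),
    M2 = c("linear", "none"),
    M3 = c("rw1", "none"),
    M4 = c("rw1", "linear"),
    M5 = c("rw1", "rw1"),
    stop("unknown model label: ", label, call. = FALSE))
  afs_spec(cohort_effect = eff[1], age_effect = eff[2], ...)
}

#' @export
print.afs_spec <- function(x, ...) {
  cat("AFS model spec:", x$distribution,
      "| cohort:", x$cohort_effect, "| age:", x$age_effect,
      "| reference age:", x$reference_age, "\n")
  invisible(x)
}

# ---- internal fitting data ------------------------------------------------

# Precompute indices and log-age terms. Out-of-range cohorts/ages are clamped
# to the nearest grid node (flat extrapolation of the latent effect). With
# aggregate = TRUE (the default, used for fitting) records sharing the same
# (cohort, age, outcome) cell are collapsed with summed weights — the
# likelihood and all its derivatives are linear in the weights, so this is
# exact and much faster on survey-sized data.
prepare_fit_data <- function(records, spec, aggregate = TRUE) {
  records <- validate_records(records)
  if (is.null(records$scaled_weight)) records <- scale_weights(records)
  cr <- spec$cohort_range
  if (is.null(cr)) cr <- range(records$birth_year)
  ar <- spec$age_range
  if (is.null(ar)) ar <- range(records$age_at_report)
  cohorts <- seq.int(cr[1], cr[2])
  ages <- seq.int(ar[1], ar[2])
  bch <- pmin(pmax(records$birth_year, cr[1]), cr[2])
  aar <- pmin(pmax(records$age_at_report, ar[1]), ar[2])
  if (any(bch != records$birth_year) || any(aar != records$age_at_report))
    warning("records outside cohort/age range: latent effects extrapolated flat")
  ev <- records$ever_sex == 1L
  tt <- ifelse(ev, records$reported_afs, records$age_at_report)
  w <- records$scaled_weight
  n_obs <- nrow(records)
  if (aggregate) {
    key <- paste(bch, aar, ev, tt)
    first <- !duplicated(key)
    wagg <- rowsum(w, key)
    w <- wagg[match(key[first], rownames(wagg)), 1]
    bch <- bch[first]; aar <- aar[first]; ev <- ev[first]; tt <- tt[first]
    ord <- order(bch, aar, ev, tt)   # record-order invariance of the fit
    w <- w[ord]; bch <- bch[ord]; aar <- aar[ord]
    ev <- ev[ord]; tt <- tt[ord]
  } else {
    w <- records$scaled_weight
  }
  list(
    n = length(tt),
    n_obs = n_obs,
    event = ev,
    l1 = log(pmax(tt, 1e-12)),          # log left endpoint / censoring age
    l2 = ifelse(ev, log(tt + 1), NA_real_),
    t0 = tt == 0,                        # event in [0, 1): F(0) = 0 exactly
    w = w,
    cohort_idx = match(bch, cohorts),
    age_idx = match(aar, ages),
    cohorts = cohorts,
    ages = ages,
    cohort_centered = cohorts - mean(cohorts),
    age_centered = ages - mean(ages),
    spec = spec
  )
}

# Parameter layout over the free (unconstrained) vector. RW1 effects are
# parameterised by their first differences: f_raw = c(0, cumsum(delta)),
# f = f_raw - mean(f_raw), which makes the sum-to-zero constraint implicit
# and the RW1 prior an iid normal on delta.
param_layout <- function(dat) {
  spec <- dat$spec
  nf <- switch(spec$cohort_effect, none = 0L, linear = 1L,
               rw1 = length(dat$cohorts) - 1L)
  nb <- switch(spec$age_effect, none = 0L, linear = 1L,
               rw1 = length(dat$ages) - 1L)
  idx <- list(beta0 = 1L)
  k <- 1L
  idx$f <- if (nf) (k + 1L):(k + nf) else integer(0); k <- k + nf
  idx$b <- if (nb) (k + 1L):(k + nb) else integer(0); k <- k + nb
  if (spec$cohort_effect == "rw1") { k <- k + 1L; idx$logtau_f <- k }
  if (spec$age_effect == "rw1") { k <- k + 1L; idx$logtau_b <- k }
  k <- k + 1L; idx$logp <- k
  if (spec$distribution == "logskewlogistic") { k <- k + 1L; idx$loggamma <- k }
  idx$npar <- k
  idx
}

rw1_expand <- function(delta) {
  f_raw <- c(0, cumsum(delta))
  f_raw - mean(f_raw)
}

# chain rule back from the full effect vector to the differences
rw1_grad_collapse <- function(g_f) {
  g0 <- g_f - mean(g_f)
  cs <- rev(cumsum(rev(g0)))
  cs[-1L]
}

# expand the free vector into natural parameters
unpack_params <- function(theta, dat, layout = param_layout(dat)) {
  spec <- dat$spec
  f <- switch(spec$cohort_effect,
    none = rep(0, length(dat$cohorts)),
    linear = theta[layout$f] * dat$cohort_centered,
    rw1 = rw1_expand(theta[layout$f]))
  b <- switch(spec$age_effect,
    none = rep(0, length(dat$ages)),
    linear = theta[layout$b] * dat$age_centered,
    rw1 = rw1_expand(theta[layout$b]))
  list(beta0 = theta[layout$beta0], f = f, b = b,
       logtau_f = if (!is.null(layout$logtau_f)) theta[layout$logtau_f],
       logtau_b = if (!is.null(layout$logtau_b)) theta[layout$logtau_b],
       p = exp(theta[layout$logp]),
       gamma = if (!is.null(layout$loggamma)) exp(theta[layout$loggamma]) else 1)
}

# ---- likelihood -----------------------------------------------------------

# Weighted interval-censored log-likelihood and its gradient with respect to
# (eta_i, log p, log gamma). Returns list(value, g_eta, g_logp, g_loggamma).
# A small positive floor guards log of an underflowed interval probability;
# occurrences are counted in the 'n_clamped' field.
loglik_core <- function(eta, p, gam, dat, want_grad = TRUE) {
  ev <- dat$event
  w <- dat$w
  n_clamped <- 0L

  value <- 0
  g_eta <- if (want_grad) numeric(dat$n)
  g_p <- 0; g_g <- 0

  if (any(ev)) {
    e1 <- eta[ev] - dat$l1[ev]
    e2 <- eta[ev] - dat$l2[ev]
    z1 <- p * e1; z2 <- p * e2
    s1 <- .log1pexp(z1); s2 <- .log1pexp(z2)   # s1 >= s2
    # F(a) = e^{-gam s1}, F(a+1) = e^{-gam s2}; events with a = 0 have F(a)=0
    s1[dat$t0[ev]] <- Inf
    F1 <- exp(-gam * s1); F2 <- exp(-gam * s2)
    ds <- pmax(s1 - s2, 0)
    logD <- -gam * s2 + log(pmax(-expm1(-gam * ds), 1e-300))
    bad <- !is.finite(logD) | logD < -690
    if (any(bad)) { n_clamped <- sum(bad); logD[bad] <- -690 }
    value <- value + sum(w[ev] * logD)
    if (want_grad) {
      D <- pmax(exp(logD), 1e-300)
      sg1 <- stats::plogis(z1); sg2 <- stats::plogis(z2)
      A1 <- F1 * sg1; A2 <- F2 * sg2          # F * sigma(z)
      A1[!is.finite(A1)] <- 0
      g_eta[ev] <- -gam * p * (A2 - A1) / D
      g_p <- g_p + sum(w[ev] * (-gam) * (A2 * e2 - ifelse(is.finite(e1 * A1), A1 * e1, 0)) / D)
      sF1 <- ifelse(is.finite(s1), F1 * s1, 0)  # F s -> 0 as s -> Inf
      g_g <- g_g + sum(w[ev] * (-(F2 * s2 - sF1)) / D)
    }
  }
  if (any(!ev)) {
    cs <- !ev
    e1 <- eta[cs] - dat$l1[cs]
    z1 <- p * e1
    s1 <- .log1pexp(z1)
    F1 <- exp(-gam * s1)
    S <- pmax(-expm1(-gam * s1), 1e-300)
    value <- value + sum(w[cs] * log(S))
    if (want_grad) {
      sg1 <- stats::plogis(z1)
      g_eta[cs] <- gam * p * F1 * sg1 / S
      g_p <- g_p + sum(w[cs] * gam * F1 * sg1 * e1 / S)
      g_g <- g_g + sum(w[cs] * F1 * s1 / S)
    }
  }
  if (want_grad) g_eta <- g_eta * w
  list(value = value, g_eta = g_eta, g_p = g_p, g_gamma = g_g,
       n_clamped = n_clamped)
}

#' Interval-censored, survey-weighted log-likelihood
#'
#' Evaluates \eqn{\sum_{d_i=1} w_i^* \log[S(T_i) - S(T_i+1)] +
#' \sum_{d_i=0} w_i^* \log S(T_i)} with the log-skew-logistic survival
#' function at each record's own rate \eqn{\lambda_i = \exp(-\eta_i)},
#' \eqn{\eta_i = \beta_0 + f(\mathrm{bch}_i) + b(\mathrm{age}_i)}, and shared
#' shape/skewness.
#'
#' @param records record data frame (weights are Kish-scaled if no
#'   `scaled_weight` column is present).
#' @param params list with elements `beta0`, `f` (per-cohort vector or NULL),
#'   `b` (per-age vector or NULL), `p`, `gamma`.
#' @param spec an [afs_spec()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(records, params, spec) {
  dat <- prepare_fit_data(records, spec)
  f <- if (is.null(params[["f"]])) rep(0, length(dat$cohorts)) else params[["f"]]
  b <- if (is.null(params[["b"]])) rep(0, length(dat$ages)) else params[["b"]]
  stopifnot(length(f) == length(dat$cohorts), length(b) == length(dat$ages))
  eta <- params[["beta0"]] + f[dat$cohort_idx] + b[dat$age_idx]
  gam <- if (is.null(params[["gamma"]])) 1 else params[["gamma"]]
  loglik_core(eta, params[["p"]], gam, dat, want_grad = FALSE)$value
}

#' Linear predictor for one or more records
#'
#' \eqn{\eta_i = \beta_0 + f(\mathrm{birth\_year}_i) +
#' b(\mathrm{age\_at\_report}_i)}; the distribution scale is \eqn{\exp(\eta)}
#' and the rate \eqn{\lambda = \exp(-\eta)}.
#'
#' @inheritParams log_likelihood
#' @export
linear_predictor <- function(records, params, spec) {
  dat <- prepare_fit_data(records, spec, aggregate = FALSE)
  f <- if (is.null(params[["f"]])) rep(0, length(dat$cohorts)) else params[["f"]]
  b <- if (is.null(params[["b"]])) rep(0, length(dat$ages)) else params[["b"]]
  params[["beta0"]] + f[dat$cohort_idx] + b[dat$age_idx]
}

# ---- priors ---------------------------------------------------------------

# PC prior on log tau: exponential(theta) on sigma = tau^{-1/2},
# theta = -log(alpha) / u; includes the Jacobian |d sigma / d log tau|.
pc_prior_logtau <- function(logtau, u, alpha) {
  theta <- -log(alpha) / u
  sigma <- exp(-logtau / 2)
  list(value = log(theta) - theta * sigma - logtau / 2 - log(2),
       grad = theta * sigma / 2 - 0.5)
}

# Penalised log-posterior = loglik + log prior, with gradient, on the free
# parameter vector. Standard normal priors on the intercept, linear slopes,
# log p and log gamma; iid N(0, 1/tau) on RW1 increments; PC prior on tau.
logpost_core <- function(theta, dat, layout) {
  spec <- dat$spec
  pp <- unpack_params(theta, dat, layout)
  eta <- pp$beta0 + pp$f[dat$cohort_idx] + pp$b[dat$age_idx]
  ll <- loglik_core(eta, pp$p, pp$gamma, dat, want_grad = TRUE)

  value <- ll$value
  grad <- numeric(layout$npar)

  # likelihood gradient mapped to free parameters
  grad[layout$beta0] <- sum(ll$g_eta)
  if (spec$cohort_effect == "linear") {
    grad[layout$f] <- sum(ll$g_eta * dat$cohort_centered[dat$cohort_idx])
  } else if (spec$cohort_effect == "rw1") {
    g_f <- numeric(length(dat$cohorts))
    agg <- rowsum(ll$g_eta, dat$cohort_idx)
    g_f[as.integer(rownames(agg))] <- agg[, 1]
    grad[layout$f] <- rw1_grad_collapse(g_f)
  }
  if (spec$age_effect == "linear") {
    grad[layout$b] <- sum(ll$g_eta * dat$age_centered[dat$age_idx])
  } else if (spec$age_effect == "rw1") {
    g_b <- numeric(length(dat$ages))
    agg <- rowsum(ll$g_eta, dat$age_idx)
    g_b[as.integer(rownames(agg))] <- agg[, 1]
    grad[layout$b] <- rw1_grad_collapse(g_b)
  }
  grad[layout$logp] <- ll$g_p * pp$p
  if (!is.null(layout$loggamma)) grad[layout$loggamma] <- ll$g_gamma * pp$gamma

  # priors
  add_norm <- function(i) {
    value <<- value - 0.5 * theta[i]^2
    grad[i] <<- grad[i] - theta[i]
  }
  add_norm(layout$beta0)
  add_norm(layout$logp)
  if (!is.null(layout$loggamma)) add_norm(layout$loggamma)
  if (spec$cohort_effect == "linear") add_norm(layout$f)
  if (spec$age_effect == "linear") add_norm(layout$b)

  add_rw1 <- function(ifree, ilogtau) {
    delta <- theta[ifree]
    tau <- exp(theta[ilogtau])
    m1 <- length(delta)
    value <<- value + 0.5 * m1 * (theta[ilogtau] - log(2 * pi)) -
      0.5 * tau * sum(delta^2)
    grad[ifree] <<- grad[ifree] - tau * delta
    pc <- pc_prior_logtau(theta[ilogtau], spec$pc_prior_u, spec$pc_prior_alpha)
    value <<- value + pc$value
    grad[ilogtau] <<- grad[ilogtau] + 0.5 * m1 -
      0.5 * tau * sum(delta^2) + pc$grad
  }
  if (spec$cohort_effect == "rw1") add_rw1(layout$f, layout$logtau_f)
  if (spec$age_effect == "rw1") add_rw1(layout$b, layout$logtau_b)

  list(value = value, grad = grad, n_clamped = ll$n_clamped)
}

#' Log prior density of a parameter configuration
#'
#' Standard normal on the intercept and any linear slopes, iid
#' \eqn{N(0, \tau^{-1})} on RW1 first differences with a
#' penalised-complexity prior on each \eqn{\tau}, and weakly-informative
#' standard normals on \eqn{\log p} and \eqn{\log\gamma}.
#'
#' @param theta free parameter vector (see [fit_afs()] for the layout).
#' @param records,spec as in [log_likelihood()].
#' @export
log_prior <- function(theta, records, spec) {
  dat <- prepare_fit_data(records, spec)
  layout <- param_layout(dat)
  lp <- logpost_core(theta, dat, layout)
  ll <- loglik_core(params_eta(theta, dat, layout),
                    exp(theta[layout$logp]),
                    if (is.null(layout$loggamma)) 1 else exp(theta[layout$loggamma]),
                    dat, want_grad = FALSE)
  lp$value - ll$value
}

params_eta <- function(theta, dat, layout) {
  pp <- unpack_params(theta, dat, layout)
  pp$beta0 + pp$f[dat$cohort_idx] + pp$b[dat$age_idx]
}
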