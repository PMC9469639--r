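# Log-skew-logistic distribution for a positive time-to-event variable T:
# log(T) follows a skew-logistic (generalised logistic) law with location
# mu = -log(rate), shape p and skewness gamma, so that
#   F(t) = [1 + (rate * t)^(-p)]^(-gamma),   t > 0.
# gamma = 1 recovers the ordinary log-logistic distribution.
# Internally everything is computed on the log scale through
#   z = p * (eta - log t),  eta = -log(rate),
# with F = exp(-gamma * log1p(e^z)), which is stable for extreme ages.

check_lsl_params <- function(rate, shape, skew) {
  if (any(!is.finite(rate)) || any(rate <= 0))
    stop("'rate' must be strictly positive", call. = FALSE)
  if (any(!is.finite(shape)) || any(shape <= 0))
    stop("'shape' must be strictly positive", call. = FALSE)
  if (any(!is.finite(skew)) || any(skew <= 0))
    stop("'skew' must be strictly positive", call. = FALSE)
  invisible(TRUE)
}

# log(1 + e^z) without overflow
.log1pexp <- function(z) {
  out <- z
  small <- z < 30
  out[small] <- log1p(exp(z[small]))
  out
}

#' The log-skew-logistic distribution
#'
#' Density, distribution function, survival, quantile function, random
#' generation and hazard for the three-parameter log-skew-logistic
#' distribution with rate \eqn{\lambda} (1/years), shape \eqn{p} and skewness
#' \eqn{\gamma}. The survival function is
#' \deqn{S(t) = 1 - [1 + (\lambda t)^{-p}]^{-\gamma},}
#' the density
#' \deqn{f(t) = t^{-1}\gamma p (\lambda t)^{-p} [1 + (\lambda t)^{-p}]^{-\gamma - 1},}
#' and the median \eqn{\lambda^{-1}(2^{1/\gamma} - 1)^{-1/p}}. With
#' \eqn{\gamma = 1} all functions reduce to the two-parameter log-logistic
#' distribution. The skewness parameter permits the asymmetric,
#' non-monotone hazard typical of age-at-first-sex data: a slow rise in
#' early adolescence, a peak in the late teens, and a flattening or decline
#' afterwards.
#'
#' @param x,q vector of ages (years), strictly positive (zero allowed in
#'   `plsl`, where F(0) = 0).
#' @param p vector of probabilities.
#' @param n number of draws.
#' @param rate positive rate parameter \eqn{\lambda}; the log-scale location
#'   is \eqn{\mu = -\log\lambda}.
#' @param shape positive shape parameter \eqn{p}.
#' @param skew positive skewness parameter \eqn{\gamma}; 1 gives the
#'   log-logistic special case.
#' @param lower.tail logical; if TRUE (default) probabilities are
#'   \eqn{P(T \le t)}, otherwise \eqn{P(T > t)}.
#' @param log,log.p logical; return log-density / log-probability.
#' @return `dlsl` the density, `plsl` the distribution (or survival)
#'   function, `qlsl` quantiles, `rlsl` random draws, `lsl_hazard` the
#'   hazard \eqn{f(t)/S(t)}.
#' @examples
#' plsl(17.434, rate = 0.05, shape = 8, skew = 0.5, lower.tail = FALSE)
#' qlsl(0.5, rate = 0.05, shape = 8, skew = 0.5)  # median ~ 17.43 years
#' @name lsl
NULL

#' @rdname lsl
#' @export
dlsl <- function(x, rate, shape, skew, log = FALSE) {
  check_lsl_params(rate, shape, skew)
  if (any(x <= 0)) stop("'x' must be strictly positive", call. = FALSE)
  z <- shape * (-log(rate) - log(x))
  s <- .log1pexp(z)
  # log f = log(gamma p / t) + z - (gamma + 1) * log(1 + e^z)
  lf <- log(skew) + log(shape) - log(x) + z - (skew + 1) * s
  if (log) lf else exp(lf)
}

#' @rdname lsl
#' @export
plsl <- function(q, rate, shape, skew, lower.tail = TRUE, log.p = FALSE) {
  check_lsl_params(rate, shape, skew)
  if (any(q < 0)) stop("'q' must be non-negative", call. = FALSE)
  lq <- ifelse(q == 0, -Inf, log(q))
  z <- shape * (-log(rate) - lq)
  lF <- -skew * .log1pexp(z)           # log F, F in (0, 1)
  if (lower.tail) {
    if (log.p) lF else exp(lF)
  } else {
    S <- -expm1(lF)
    if (log.p) log(S) else S
  }
}

#' @rdname lsl
#' @export
qlsl <- function(p, rate, shape, skew) {
  check_lsl_params(rate, shape, skew)
  if (any(p <= 0 | p >= 1)) stop("'p' must be in (0, 1)", call. = FALSE)
  (p^(-1 / skew) - 1)^(-1 / shape) / rate
}

#' @rdname lsl
#' @export
rlsl <- function(n, rate, shape, skew) {
  check_lsl_params(rate, shape, skew)
  qlsl(stats::runif(n), rate = rate, shape = shape, skew = skew)
}

#' @rdname lsl
#' @export
lsl_hazard <- function(x, rate, shape, skew) {
  f <- dlsl(x, rate, shape, skew)
  S <- plsl(x, rate, shape, skew, lower.tail = FALSE)
  h <- f / S
  if (any(S == 0)) {
    warning("survival underflowed to 0; hazard set to +Inf")
    h[S == 0] <- Inf
  }
  h
}

#' Median of the log-skew-logistic distribution
#'
#' Closed form \eqn{\lambda^{-1} (2^{1/\gamma} - 1)^{-1/p}}.
#'
#' @inheritParams lsl
#' @export
lsl_median <- function(rate, shape, skew) {
  check_lsl_params(rate, shape, skew)
  (2^(1 / skew) - 1)^(-1 / shape) / rate
}

#' Rate parameter giving a target median
#'
#' Inverts the median formula: the rate \eqn{\lambda} for which the
#' log-skew-logistic distribution with given shape and skewness has median
#' `median`.
#'
#' @param median target median age (years).
#' @inheritParams lsl
#' @export
lsl_rate_for_median <- function(median, shape, skew) {
  if (any(median <= 0)) stop("'median' must be positive", call. = FALSE)
  (2^(1 / skew) - 1)^(-1 / shape) / median
}

# ---- generalised gamma (location mu, scale sigma > 0, shape Q) -------------
# Parameterisation with gamma (Q = sigma) and log-normal (Q = 0) as special
# cases: if W = (log t - mu) / sigma then Q^{-2} e^{QW} ~ Gamma(Q^{-2}, 1).
# A gamma(shape k, rate r) corresponds to sigma = Q = 1/sqrt(k), mu = log(k/r).
pgengamma <- function(q, mu, sigma, Q, lower.tail = TRUE) {
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (any(q <= 0)) stop("'q' must be strictly positive", call. = FALSE)
  if (abs(Q) < 1e-12)
    return(stats::plnorm(q, meanlog = mu, sdlog = sigma, lower.tail = lower.tail))
  w <- (log(q) - mu) / sigma
  u <- exp(Q * w) / Q^2
  if (Q > 0) stats::pgamma(u, shape = 1 / Q^2, lower.tail = lower.tail)
  else stats::pgamma(u, shape = 1 / Q^2, lower.tail = !lower.tail)
}

.dist_families <- list(
  gamma           = 2L,
  lognormal       = 2L,
  loglogistic     = 2L,
  gengamma        = 3L,
  logskewlogistic = 3L
)

#' Survival function of a named parametric family
#'
#' Dispatches to one of the five candidate distributions for the AFS
#' distribution of a birth cohort: gamma (shape, rate), log-normal (meanlog,
#' sdlog), log-logistic (rate, shape), generalised gamma (mu, sigma, Q) and
#' log-skew-logistic (rate, shape, skew). The log-logistic is the
#' skew = 1 special case of the log-skew-logistic; the generalised gamma
#' contains the gamma (Q = sigma) and log-normal (Q = 0) as special cases.
#'
#' @param name family name, one of `"gamma"`, `"lognormal"`,
#'   `"loglogistic"`, `"gengamma"`, `"logskewlogistic"`.
#' @param params numeric parameter vector of the length the family requires
#'   (2 or 3, in the order listed above).
#' @param t ages at which to evaluate the survival function.
#' @return numeric vector of survival probabilities \eqn{P(T > t)}.
#' @export
dist_survival <- function(name, params, t) {
  np <- .dist_families[[name]]
  if (is.null(np))
    stop("unknown distribution family: '", name, "'", call. = FALSE)
  if (length(params) != np)
    stop("family '", name, "' needs ", np, " parameters, got ",
         length(params), call. = FALSE)
  switch(name,
    gamma = stats::pgamma(t, shape = params[1], rate = params[2],
                          lower.tail = FALSE),
    lognormal = stats::plnorm(t, meanlog = params[1], sdlog = params[2],
                              lower.tail = FALSE),
    loglogistic = plsl(t, rate = params[1], shape = params[2], skew = 1,
                       lower.tail = FALSE),
    gengamma = pgengamma(t, mu = params[1], sigma = params[2], Q = params[3],
                         lower.tail = FALSE),
    logskewlogistic = plsl(t, rate = params[1], shape = params[2],
                           skew = params[3], lower.tail = FALSE)
  )
}
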