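# Analytic Hessian of the penalised log-posterior with respect to the
# "inner" parameters (intercept, effect coefficients, log p, log gamma) at
# fixed RW1 log-precisions. Needed cheaply and repeatedly by the Laplace
# marginal used to estimate the precisions, and once more at the mode for
# the posterior covariance.
#
# All second derivatives flow through F(t) = exp(-gamma * s(z)),
# z = p * (eta - log t), s = log(1 + e^z), sigma = plogis(z):
#   F_eta    = -gamma p sigma F
#   F_lp     = -gamma z sigma F                (lp = log p)
#   F_lg     = -gamma s F                      (lg = log gamma)
#   F_etaeta = p^2 gamma F sigma (gamma sigma - 1 + sigma)
#   F_etalp  = -gamma p sigma F [1 + z (1 - sigma - gamma sigma)]
#   F_lplp   = -gamma z sigma F [1 + z (1 - sigma - gamma sigma)]
#   F_etalg  = -gamma p sigma F (1 - gamma s)
#   F_lplg   = -gamma z sigma F (1 - gamma s)
#   F_lglg   = -gamma s F (1 - gamma s)
# Event records use l = log(F2 - F1); censored use l = log(1 - F1).

fderivs <- function(z, gam, p) {
  s <- .log1pexp(z)
  sg <- stats::plogis(z)
  F <- exp(-gam * s)
  zF <- ifelse(is.finite(z), z, 0)   # F = 0 kills the infinite-z branch
  sF <- ifelse(is.finite(s), s, 0)
  list(
    F = F,
    e = -gam * p * sg * F,
    lp = -gam * zF * sg * F,
    lg = -gam * sF * F,
    ee = p^2 * gam * F * sg * (gam * sg - 1 + sg),
    elp = -gam * p * sg * F * (1 + zF * (1 - sg - gam * sg)),
    lplp = -gam * zF * sg * F * (1 + zF * (1 - sg - gam * sg)),
    elg = -gam * p * sg * F * (1 - gam * sF),
    lplg = -gam * zF * sg * F * (1 - gam * sF),
    lglg = -gam * sF * F * (1 - gam * sF)
  )
}

# Per-cell second derivatives of the weighted log-likelihood. Returns
# vectors h_ee, h_elp, h_elg (per cell, weight included) and the summed
# scalars for the (lp, lg) block.
hess_core <- function(eta, p, gam, dat) {
  ev <- dat$event
  w <- dat$w
  n <- dat$n
  h_ee <- numeric(n); h_elp <- numeric(n); h_elg <- numeric(n)
  s_lplp <- 0; s_lplg <- 0; s_lglg <- 0

  if (any(ev)) {
    z1 <- p * (eta[ev] - dat$l1[ev]); z1[dat$t0[ev]] <- Inf
    z2 <- p * (eta[ev] - dat$l2[ev])
    d1 <- fderivs(z1, gam, p)
    d2 <- fderivs(z2, gam, p)
    D <- pmax(d2$F - d1$F, 1e-300)
    ab <- function(Da, Db, Dab) Dab / D - Da * Db / D^2
    De <- d2$e - d1$e; Dlp <- d2$lp - d1$lp; Dlg <- d2$lg - d1$lg
    h_ee[ev] <- w[ev] * ab(De, De, d2$ee - d1$ee)
    h_elp[ev] <- w[ev] * ab(De, Dlp, d2$elp - d1$elp)
    h_elg[ev] <- w[ev] * ab(De, Dlg, d2$elg - d1$elg)
    s_lplp <- s_lplp + sum(w[ev] * ab(Dlp, Dlp, d2$lplp - d1$lplp))
    s_lplg <- s_lplg + sum(w[ev] * ab(Dlp, Dlg, d2$lplg - d1$lplg))
    s_lglg <- s_lglg + sum(w[ev] * ab(Dlg, Dlg, d2$lglg - d1$lglg))
  }
  if (any(!ev)) {
    cs <- !ev
    z1 <- p * (eta[cs] - dat$l1[cs])
    d1 <- fderivs(z1, gam, p)
    S <- pmax(-expm1(-gam * .log1pexp(z1)), 1e-300)
    ab <- function(Da, Db, Dab) -Dab / S - Da * Db / S^2
    h_ee[cs] <- w[cs] * ab(d1$e, d1$e, d1$ee)
    h_elp[cs] <- w[cs] * ab(d1$e, d1$lp, d1$elp)
    h_elg[cs] <- w[cs] * ab(d1$e, d1$lg, d1$elg)
    s_lplp <- s_lplp + sum(w[cs] * ab(d1$lp, d1$lp, d1$lplp))
    s_lplg <- s_lplg + sum(w[cs] * ab(d1$lp, d1$lg, d1$lplg))
    s_lglg <- s_lglg + sum(w[cs] * ab(d1$lg, d1$lg, d1$lglg))
  }
  list(h_ee = h_ee, h_elp = h_elp, h_elg = h_elg,
       s_lplp = s_lplp, s_lplg = s_lplg, s_lglg = s_lglg)
}

# Effect design matrix mapping free coefficients to the per-node effect:
# rw1 -> centred cumulative-sum basis, linear -> centred covariate column.
effect_basis <- function(kind, m, centered) {
  if (kind == "none") return(NULL)
  if (kind == "linear") return(matrix(centered, ncol = 1))
  L <- matrix(0, m, m - 1)
  L[lower.tri(L)] <- 1   # L[j, k] = 1 iff k < j
  sweep(L, 2, colMeans(L))
}

# aggregate a per-cell vector to per-node totals
agg_nodes <- function(v, idx, m) {
  out <- numeric(m)
  a <- rowsum(v, idx)
  out[as.integer(rownames(a))] <- a[, 1]
  out
}

# Negative Hessian of the penalised log-posterior over the inner parameter
# coordinates (everything except the RW1 log-precisions), at theta.
hess_inner <- function(theta, dat, layout) {
  spec <- dat$spec
  pp <- unpack_params(theta, dat, layout)
  eta <- pp$beta0 + pp$f[dat$cohort_idx] + pp$b[dat$age_idx]
  hc <- hess_core(eta, pp$p, pp$gamma, dat)
  # map lp to actual log p: derivatives above are already with respect to
  # log p and log gamma (z and s carry the chain rule through z = p * e).
  mf <- length(dat$cohorts); mb <- length(dat$ages)
  Cf <- effect_basis(spec$cohort_effect, mf, dat$cohort_centered)
  Cb <- effect_basis(spec$age_effect, mb, dat$age_centered)
  inner <- c(layout$beta0, layout$f, layout$b, layout$logp, layout$loggamma)
  d <- length(inner)
  H <- matrix(0, d, d)
  ib0 <- 1L
  if_ <- if (length(layout$f)) 1L + seq_along(layout$f) else integer(0)
  ib <- if (length(layout$b)) 1L + length(layout$f) + seq_along(layout$b)
        else integer(0)
  ilp <- 1L + length(layout$f) + length(layout$b) + 1L
  ilg <- if (!is.null(layout$loggamma)) ilp + 1L else NULL

  A_c <- agg_nodes(hc$h_ee, dat$cohort_idx, mf)      # per-cohort sums
  A_a <- agg_nodes(hc$h_ee, dat$age_idx, mb)
  H[ib0, ib0] <- sum(hc$h_ee)
  H[ib0, ilp] <- H[ilp, ib0] <- sum(hc$h_elp)
  H[ilp, ilp] <- hc$s_lplp
  if (!is.null(ilg)) {
    H[ib0, ilg] <- H[ilg, ib0] <- sum(hc$h_elg)
    H[ilp, ilg] <- H[ilg, ilp] <- hc$s_lplg
    H[ilg, ilg] <- hc$s_lglg
  }
  if (length(if_)) {
    H[if_, if_] <- crossprod(Cf, Cf * A_c)
    H[ib0, if_] <- H[if_, ib0] <- crossprod(Cf, A_c)
    H[if_, ilp] <- H[ilp, if_] <-
      crossprod(Cf, agg_nodes(hc$h_elp, dat$cohort_idx, mf))
    if (!is.null(ilg))
      H[if_, ilg] <- H[ilg, if_] <-
        crossprod(Cf, agg_nodes(hc$h_elg, dat$cohort_idx, mf))
  }
  if (length(ib)) {
    H[ib, ib] <- crossprod(Cb, Cb * A_a)
    H[ib0, ib] <- H[ib, ib0] <- crossprod(Cb, A_a)
    H[ib, ilp] <- H[ilp, ib] <-
      crossprod(Cb, agg_nodes(hc$h_elp, dat$age_idx, mb))
    if (!is.null(ilg))
      H[ib, ilg] <- H[ilg, ib] <-
        crossprod(Cb, agg_nodes(hc$h_elg, dat$age_idx, mb))
  }
  if (length(if_) && length(ib)) {
    # cohort x age cross block through the shared eta
    key <- (dat$cohort_idx - 1L) * mb + dat$age_idx
    X <- matrix(0, mf, mb)
    a <- rowsum(hc$h_ee, key)
    k <- as.integer(rownames(a))
    X[cbind((k - 1L) %/% mb + 1L, (k - 1L) %% mb + 1L)] <- a[, 1]
    H[if_, ib] <- crossprod(Cf, X %*% Cb)
    H[ib, if_] <- t(H[if_, ib])
  }

  # priors: N(0,1) on intercept, slopes, log p, log gamma; tau I on RW1
  # increments (second derivative of the log prior is -1 resp. -tau)
  Hp <- numeric(d)
  Hp[ib0] <- 1
  Hp[ilp] <- 1
  if (!is.null(ilg)) Hp[ilg] <- 1
  if (spec$cohort_effect == "linear") Hp[if_] <- 1
  if (spec$cohort_effect == "rw1") Hp[if_] <- exp(theta[layout$logtau_f])
  if (spec$age_effect == "linear") Hp[ib] <- 1
  if (spec$age_effect == "rw1") Hp[ib] <- exp(theta[layout$logtau_b])

  list(negH = -(H - diag(Hp, d)), inner = inner)
}
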