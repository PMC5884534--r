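# Marginalized dynamic-occupancy likelihood.
#
# For models whose parameters depend only on site covariates (no
# auto-covariate), the latent chain z(i, .) is independent across sites and
# the likelihood marginalizes exactly by a forward recursion over the
# two-state chain: season-1 prior (psi1, 1 - psi1), transition rows
# [(1 - gamma, gamma), (epsilon, 1 - epsilon)], and per-season emissions
# prod_k p^y (1-p)^(1-y) for z = 1 or the all-zero indicator for z = 0.
# Missing observations contribute emission 1.

# Per site-season sufficient statistics of the observations.
emission_stats <- function(history) {
  y <- history$y
  nobs <- apply(!is.na(y), c(1, 2), sum)
  sumy <- apply(y, c(1, 2), sum, na.rm = TRUE)
  list(nobs = nobs, sumy = sumy, n = dim(y)[1], T = dim(y)[2])
}

# Probability-scale parameter fields from a flat logit-scale vector.
prob_fields <- function(theta, mats) {
  sp <- split_params(theta, mats)
  list(psi1 = inv_logit(drop(mats$X$psi1 %*% sp$psi1)),
       gamma = if (mats$npar[["gamma"]] > 0)
         inv_logit(drop(mats$X$gamma %*% sp$gamma)) else NULL,
       epsilon = if (mats$npar[["epsilon"]] > 0)
         inv_logit(drop(mats$X$epsilon %*% sp$epsilon)) else NULL,
       p = inv_logit(drop(mats$X$p %*% sp$p)))
}

# Forward recursion; returns the log-likelihood and (optionally) the
# normalized filtered state probabilities needed for backward sampling.
forward_marginal <- function(theta, mats, es, keep_filter = FALSE) {
  pf <- prob_fields(theta, mats)
  n <- es$n; Tn <- es$T
  e1 <- matrix(pf$p, n, Tn)^es$sumy * matrix(1 - pf$p, n, Tn)^(es$nobs - es$sumy)
  e0 <- (es$sumy == 0) * 1
  a1 <- pf$psi1 * e1[, 1]
  a0 <- (1 - pf$psi1) * e0[, 1]
  s <- a1 + a0
  ll <- log(s)
  if (keep_filter) {
    f1 <- matrix(NA_real_, n, Tn)
    f1[, 1] <- a1 / s
  }
  a1 <- a1 / s; a0 <- a0 / s
  if (Tn > 1) for (t in 2:Tn) {
    b1 <- (a1 * (1 - pf$epsilon) + a0 * pf$gamma) * e1[, t]
    b0 <- (a1 * pf$epsilon + a0 * (1 - pf$gamma)) * e0[, t]
    s <- b1 + b0
    ll <- ll + log(s)
    a1 <- b1 / s; a0 <- b0 / s
    if (keep_filter) f1[, t] <- a1
  }
  out <- list(loglik = sum(ll), site_loglik = ll)
  if (keep_filter) out$f1 <- f1
  out
}

#' Exact marginal log-likelihood of a dynamic occupancy model
#'
#' Computes the dynamic-occupancy likelihood with the latent states summed
#' out by a per-site forward recursion over the two-state chain. Only valid
#' for specifications without the auto-covariate (which couples sites through
#' their neighbours' latent states and breaks the site-wise factorization).
#'
#' @param params Flat coefficient vector on the logit scale, ordered
#'   `psi1, gamma, epsilon, p` blocks (column order of the model matrices;
#'   for single-season data the `gamma`/`epsilon` blocks are absent).
#' @param spec An [occu_spec()] without auto-covariate terms.
#' @param history A `detection_history`.
#' @param stations Station table (standardize covariates beforehand if the
#'   coefficients are on the standardized scale).
#' @return The log-likelihood (scalar).
#' @export
dynamic_loglik <- function(params, spec, history, stations) {
  if (length(spec$auto))
    stopf("marginal likelihood unavailable with the auto-covariate; fit with the latent-state sampler")
  if (any(!is.finite(params))) stopf("non-finite parameters")
  stn <- stations[match(dimnames(history$y)[[1]], stations$id), , drop = FALSE]
  mats <- build_mats(spec, stn, single_season = dim(history$y)[2] == 1)
  if (length(params) != sum(mats$npar))
    stopf("expected %d parameters (%s), got %d", sum(mats$npar),
          paste(mats$par_names, collapse = ", "), length(params))
  forward_marginal(params, mats, emission_stats(history))$loglik
}

# Model matrices with the gamma/epsilon blocks dropped for single-season data.
build_mats <- function(spec, stations, single_season = FALSE) {
  mats <- spec_matrices(spec, stations)
  if (single_season) {
    mats$npar[c("gamma", "epsilon")] <- 0L
    keep <- !grepl("^(gamma|epsilon)\\.", mats$par_names)
    mats$par_names <- mats$par_names[keep]
    mats$offsets <- cumsum(c(0, mats$npar))[1:4]
  }
  mats
}

# Backward (FFBS) draw of the latent states given parameters; vectorized over
# sites. Returns an n x T integer matrix.
ffbs_draw <- function(theta, mats, es) {
  fw <- forward_marginal(theta, mats, es, keep_filter = TRUE)
  pf <- prob_fields(theta, mats)
  n <- es$n; Tn <- es$T
  z <- matrix(0L, n, Tn)
  z[, Tn] <- stats::rbinom(n, 1, fw$f1[, Tn])
  if (Tn > 1) for (t in (Tn - 1):1) {
    f1 <- fw$f1[, t]
    # P(z_t = 1 | z_{t+1}, y_{1:t})
    w1 <- f1 * ifelse(z[, t + 1] == 1, 1 - pf$epsilon, pf$epsilon)
    w0 <- (1 - f1) * ifelse(z[, t + 1] == 1, pf$gamma, 1 - pf$gamma)
    z[, t] <- stats::rbinom(n, 1, w1 / (w1 + w0))
  }
  z
}

# Joint log p(z, y | theta) for the latent-state sampler; D columns (one per
# transition, from z at t-1) are supplied when the spec has the auto-covariate.
loglik_given_z <- function(theta, mats, es, z, spec, D = NULL) {
  pf <- prob_fields(theta, mats)
  sp <- split_params(theta, mats)
  n <- es$n; Tn <- es$T
  lp <- sum(stats::dbinom(z[, 1], 1, pf$psi1, log = TRUE))
  if (Tn > 1) {
    a_g <- if ("gamma" %in% spec$auto) sp$gamma[length(sp$gamma)] else 0
    a_e <- if ("epsilon" %in% spec$auto) sp$epsilon[length(sp$epsilon)] else 0
    eta_g0 <- drop(mats$X$gamma %*% sp$gamma[seq_len(ncol(mats$X$gamma))])
    eta_e0 <- drop(mats$X$epsilon %*% sp$epsilon[seq_len(ncol(mats$X$epsilon))])
    for (t in 2:Tn) {
      d <- if (is.null(D)) 0 else D[, t - 1]
      g <- inv_logit(eta_g0 + a_g * d)
      e <- inv_logit(eta_e0 + a_e * d)
      pr <- z[, t - 1] * (1 - e) + (1 - z[, t - 1]) * g
      lp <- lp + sum(stats::dbinom(z[, t], 1, pr, log = TRUE))
    }
  }
  lp + obs_loglik_given_z(pf$p, es, z)
}

# log p(y | z, p): detection terms only (the "conditional" deviance scale).
obs_loglik_given_z <- function(p_site, es, z) {
  q <- matrix(p_site, es$n, es$T) * z
  ll <- ifelse(es$sumy > 0,
               ifelse(q > 0, es$sumy * log(q), -Inf),
               0) +
        ifelse(es$nobs - es$sumy > 0, (es$nobs - es$sumy) * log1p(-q), 0)
  sum(ll)
}
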