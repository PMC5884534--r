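#' MCMC settings for occupancy model fitting
#'
#' Defaults are test-scale (3 chains, 2000 kept draws after 500 adaptation/
#' burn-in iterations); `paper_scale = TRUE` switches to the survey-scale
#' convention of 3 chains with 100,000 kept draws after a 20,000 burn-in.
#'
#' @param n_chains Number of chains (>= 2 for convergence diagnostics).
#' @param n_iter Kept iterations per chain.
#' @param n_burn Burn-in (and proposal-adaptation) iterations per chain.
#' @param prior_sd Prior standard deviation of every logit-scale coefficient
#'   (Normal, mean 0). The default 31.6 matches the diffuse precision-0.001
#'   convention of standard Bayesian occupancy workflows.
#' @param z_draws Number of posterior draws of the latent states retained for
#'   derived quantities (capped at the kept draws).
#' @param rhat_threshold Gelman-Rubin threshold above which a fit is flagged
#'   as non-converged (default 1.1).
#' @param paper_scale Use the survey-scale iteration counts.
#' @param seed Integer seed.
#' @return An `mcmc_control` list.
#' @export
mcmc_control <- function(n_chains = 3, n_iter = 2000, n_burn = 500,
                         prior_sd = 31.6, z_draws = 1000,
                         rhat_threshold = 1.1, paper_scale = FALSE, seed = 1L) {
  if (paper_scale) {
    n_iter <- 100000
    n_burn <- 20000
    n_chains <- 3
  }
  list(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
       prior_sd = prior_sd, z_draws = z_draws,
       rhat_threshold = rhat_threshold, seed = as.integer(seed))
}

#' Fit a Bayesian occupancy model by MCMC
#'
#' Fits the hierarchical occupancy model defined by an [occu_spec()] to a
#' detection history. Covariates named in the specification are standardized
#' internally (mean 0, sample sd 1) and the scaling is stored for
#' back-transforming response curves. Two engines are used:
#'
#' * **marginal** (no auto-covariate): adaptive random-walk Metropolis on the
#'   exact marginalized likelihood; latent-state draws are recovered
#'   afterwards by forward-filter backward-sampling.
#' * **latent** (auto-covariate present): single-site Gibbs updates of the
#'   latent states from their full conditionals (including the neighbour
#'   terms through which a state enters other sites' dynamics) alternating
#'   with Metropolis updates of the coefficients.
#'
#' Priors are independent Normal(0, `prior_sd`) on all logit-scale
#' coefficients. Convergence is assessed by split Gelman-Rubin diagnostics;
#' a fit with any R-hat above the threshold is flagged (not an error).
#'
#' @param spec An [occu_spec()].
#' @param history A `detection_history` (subset seasons first if needed).
#' @param stations Station table on the raw covariate scale.
#' @param graph Neighbour graph, required when the spec has the
#'   auto-covariate.
#' @param control An [mcmc_control()].
#' @param flagged Optional collinearity table; refuses flagged pairs.
#' @return An `occufit` object.
#' @export
fit_occu <- function(spec, history, stations, graph = NULL,
                     control = mcmc_control(), flagged = NULL) {
  if (!is.null(flagged)) {
    for (par in c("psi1", "gamma", "epsilon", "p"))
      if (uses_flagged_pair(spec_terms(spec, par), flagged))
        stopf("spec %s uses a collinearity-flagged pair", par)
  }
  ids <- dimnames(history$y)[[1]]
  stn_raw <- stations[match(ids, stations$id), , drop = FALSE]
  used <- unique(gsub("^I\\(|\\^2\\)$", "",
                      unlist(lapply(c("psi1", "gamma", "epsilon", "p"),
                                    function(par) spec_terms(spec, par)))))
  used <- used[vapply(used, function(u)
    u %in% names(stn_raw) && is.numeric(stn_raw[[u]]), logical(1))]
  if (length(used)) {
    stdz <- standardize_covariates(stn_raw, used)
    stn <- stdz$stations
    scaling <- stdz$scaling
  } else {
    stn <- stn_raw
    scaling <- NULL
  }
  single <- dim(history$y)[2] == 1
  if (single && length(spec$auto))
    stopf("auto-covariate requires at least two seasons")
  mats <- build_mats(spec, stn, single_season = single)
  es <- emission_stats(history)
  engine <- if (length(spec$auto)) "latent" else "marginal"
  if (engine == "latent" && is.null(graph))
    stopf("auto-covariate models need a neighbor graph")

  t0 <- proc.time()[3]
  res <- if (engine == "marginal")
    run_marginal_mcmc(mats, es, control)
  else
    run_latent_mcmc(mats, es, spec, history, graph, control)

  rhat <- gelman_rubin(res$chains)
  samples <- do.call(rbind, res$chains)
  colnames(samples) <- mats$par_names
  theta_bar <- colMeans(samples)

  if (engine == "marginal") {
    nz <- min(control$z_draws, nrow(samples))
    idx <- unique(round(seq(1, nrow(samples), length.out = nz)))
    z_draws <- array(0L, c(length(idx), es$n, es$T))
    for (j in seq_along(idx))
      z_draws[j, , ] <- ffbs_draw(samples[idx[j], ], mats, es)
    deviance_at_mean <- -2 * forward_marginal(theta_bar, mats, es)$loglik
  } else {
    z_draws <- res$z_draws
    pbar <- inv_logit(drop(mats$X$p %*%
                             split_params(theta_bar, mats)$p))
    qbar <- res$qbar  # posterior mean of z * p per site-season
    ll <- ifelse(es$sumy > 0, ifelse(qbar > 0, es$sumy * log(qbar), -Inf), 0) +
      ifelse(es$nobs - es$sumy > 0, (es$nobs - es$sumy) * log1p(-qbar), 0)
    deviance_at_mean <- -2 * sum(ll)
  }
  pao_draws <- t(apply(z_draws, 1, colMeans))
  if (es$T == 1) pao_draws <- matrix(pao_draws, ncol = 1)
  colnames(pao_draws) <- dimnames(history$y)[[2]]

  structure(list(
    spec = spec, engine = engine, mats = mats, history = history,
    stations = stn_raw, stations_std = stn, scaling = scaling, graph = graph,
    chains = res$chains, samples = samples, deviance = res$deviance,
    deviance_at_mean = deviance_at_mean,
    z_draws = z_draws, pao_draws = pao_draws,
    rhat = rhat, converged = all(rhat < control$rhat_threshold, na.rm = TRUE),
    accept_rate = res$accept_rate, control = control,
    runtime = proc.time()[3] - t0), class = "occufit")
}

#' @rdname fit_occu
#' @export
fit_dynamic <- function(spec, history, stations, graph = NULL,
                        control = mcmc_control(), flagged = NULL) {
  if (dim(history$y)[2] < 2)
    stopf("dynamic model needs >= 2 seasons; use fit_single_season")
  fit_occu(spec, history, stations, graph, control, flagged)
}

#' Fit a single-season occupancy model
#'
#' Collapses the model to occupancy and detection only (`psi`, `p`).
#'
#' @param spec An [occu_spec()]; only its `psi1` and `p` formulas are used.
#' @param history A one-season `detection_history` (subset with
#'   [subset_history()]).
#' @param stations Station table.
#' @param control An [mcmc_control()].
#' @param flagged Optional collinearity table.
#' @return An `occufit`.
#' @export
fit_single_season <- function(spec, history, stations,
                              control = mcmc_control(), flagged = NULL) {
  if (dim(history$y)[2] != 1)
    stopf("history must hold exactly one season")
  fit_occu(occu_spec(psi1 = spec$psi1, p = spec$p), history, stations,
           graph = NULL, control = control, flagged = flagged)
}

# ---- marginal engine ------------------------------------------------------

log_post_marginal <- function(theta, mats, es, prior_sd) {
  forward_marginal(theta, mats, es)$loglik +
    sum(stats::dnorm(theta, 0, prior_sd, log = TRUE))
}

run_marginal_mcmc <- function(mats, es, control) {
  d <- sum(mats$npar)
  chains <- vector("list", control$n_chains)
  deviance <- NULL
  acc_all <- numeric(0)
  for (ch in seq_len(control$n_chains)) {
    set.seed(derive_seed(control$seed, 100 + ch))
    theta <- stats::rnorm(d, 0, 0.5)
    lp <- log_post_marginal(theta, mats, es, control$prior_sd)
    scale <- 2.38 / sqrt(d)
    sigma <- diag(0.25, d)
    chol_s <- chol(sigma)
    hist_burn <- matrix(NA_real_, control$n_burn, d)
    n_acc <- 0L
    # adaptation during burn-in only; the kernel is frozen afterwards
    for (it in seq_len(control$n_burn)) {
      prop <- theta + scale * drop(stats::rnorm(d) %*% chol_s)
      lp_prop <- log_post_marginal(prop, mats, es, control$prior_sd)
      if (log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; n_acc <- n_acc + 1L
      }
      hist_burn[it, ] <- theta
      if (it %% 50 == 0) {
        scale <- scale * exp((n_acc / it - 0.234))
        if (it >= 150) {
          emp <- stats::cov(hist_burn[seq_len(it), , drop = FALSE])
          sigma <- emp + diag(1e-6, d)
          chol_s <- tryCatch(chol(sigma), error = function(e) chol(diag(0.25, d)))
        }
      }
    }
    draws <- matrix(NA_real_, control$n_iter, d)
    dev <- numeric(control$n_iter)
    n_acc <- 0L
    for (it in seq_len(control$n_iter)) {
      prop <- theta + scale * drop(stats::rnorm(d) %*% chol_s)
      lp_prop <- log_post_marginal(prop, mats, es, control$prior_sd)
      if (log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; n_acc <- n_acc + 1L
      }
      draws[it, ] <- theta
      dev[it] <- -2 * (lp - sum(stats::dnorm(theta, 0, control$prior_sd,
                                             log = TRUE)))
    }
    chains[[ch]] <- draws
    deviance <- c(deviance, dev)
    acc_all <- c(acc_all, n_acc / control$n_iter)
  }
  list(chains = chains, deviance = deviance, accept_rate = mean(acc_all))
}

# ---- latent-state engine --------------------------------------------------

run_latent_mcmc <- function(mats, es, spec, history, graph, control) {
  n <- es$n; Tn <- es$T
  d <- sum(mats$npar)
  any1 <- es$sumy > 0
  nb <- graph$neighbors
  n_nb <- graph$n
  if (any(n_nb == 0))
    warnf("%d isolated site(s): auto-covariate fixed at 0 there", sum(n_nb == 0))
  has_g <- "gamma" %in% spec$auto
  has_e <- "epsilon" %in% spec$auto

  chains <- vector("list", control$n_chains)
  deviance <- NULL
  acc_all <- numeric(0)
  keep_z <- max(1L, floor(control$n_iter * control$n_chains / control$z_draws))
  z_store <- list()
  qsum <- matrix(0, n, Tn)
  qn <- 0L

  for (ch in seq_len(control$n_chains)) {
    set.seed(derive_seed(control$seed, 200 + ch))
    theta <- stats::rnorm(d, 0, 0.5)
    z <- matrix(ifelse(any1, 1L, stats::rbinom(n * Tn, 1, 0.5)), n, Tn)
    # S[j, t] = sum of z over the neighbours of j (for D = S / n_nb)
    S <- vapply(seq_len(Tn), function(t)
      vapply(seq_len(n), function(j)
        if (n_nb[j] == 0) 0 else sum(z[nb[[j]], t]), numeric(1)),
      numeric(n))
    S <- matrix(S, n, Tn)
    Dmat <- function() {
      D <- S / pmax(n_nb, 1)
      D[n_nb == 0, ] <- 0
      D
    }
    lp <- loglik_given_z(theta, mats, es, z, spec, Dmat()) +
      sum(stats::dnorm(theta, 0, control$prior_sd, log = TRUE))
    scale <- 2.38 / sqrt(d)
    sd_vec <- rep(0.5, d)
    n_acc <- 0L; n_try <- 0L
    draws <- matrix(NA_real_, control$n_iter, d)
    dev <- numeric(control$n_iter)

    for (it in seq_len(control$n_burn + control$n_iter)) {
      # --- z sweep: exact full conditionals, single-site updates
      sp <- split_params(theta, mats)
      pf_p <- inv_logit(drop(mats$X$p %*% sp$p))
      psi1 <- inv_logit(drop(mats$X$psi1 %*% sp$psi1))
      a_g <- if (has_g) sp$gamma[length(sp$gamma)] else 0
      a_e <- if (has_e) sp$epsilon[length(sp$epsilon)] else 0
      eta_g0 <- drop(mats$X$gamma %*% sp$gamma[seq_len(ncol(mats$X$gamma))])
      eta_e0 <- drop(mats$X$epsilon %*% sp$epsilon[seq_len(ncol(mats$X$epsilon))])
      g_of <- function(i, dval) inv_logit(eta_g0[i] + a_g * dval)
      e_of <- function(i, dval) inv_logit(eta_e0[i] + a_e * dval)
      D_of <- function(i, t) if (n_nb[i] == 0) 0 else S[i, t] / n_nb[i]
      trans_lp <- function(i, z_from, z_to, dval) {
        pr <- if (z_from == 1) 1 - e_of(i, dval) else g_of(i, dval)
        if (z_to == 1) log(pr) else log1p(-pr)
      }
      for (t in seq_len(Tn)) {
        for (i in seq_len(n)) {
          if (any1[i, t]) next  # a detection forces z = 1 (set at init)
          lo <- 0
          # emission (no detections observed)
          lo <- lo + es$nobs[i, t] * log1p(-pf_p[i])
          # own prior
          lo <- lo + if (t == 1) logit(psi1[i])
                     else trans_lp(i, z[i, t - 1], 1L, D_of(i, t - 1)) -
                          trans_lp(i, z[i, t - 1], 0L, D_of(i, t - 1))
          # own future
          if (t < Tn)
            lo <- lo + trans_lp(i, 1L, z[i, t + 1], D_of(i, t)) -
                       trans_lp(i, 0L, z[i, t + 1], D_of(i, t))
          # neighbours' futures: z[i,t] enters D_{j,t} for j with i in N_j
          if (t < Tn && (has_g || has_e) && n_nb[i] > 0) {
            for (j in nb[[i]]) {
              s_other <- S[j, t] - z[i, t]
              d1 <- (s_other + 1) / n_nb[j]
              d0 <- s_other / n_nb[j]
              lo <- lo + trans_lp(j, z[j, t], z[j, t + 1], d1) -
                         trans_lp(j, z[j, t], z[j, t + 1], d0)
            }
          }
          znew <- stats::rbinom(1, 1, inv_logit(lo))
          if (znew != z[i, t]) {
            delta <- znew - z[i, t]
            z[i, t] <- znew
            if (n_nb[i] > 0) for (j in nb[[i]]) S[j, t] <- S[j, t] + delta
          }
        }
      }
      lp <- loglik_given_z(theta, mats, es, z, spec, Dmat()) +
        sum(stats::dnorm(theta, 0, control$prior_sd, log = TRUE))

      # --- theta update: joint random-walk Metropolis given z
      prop <- theta + scale * stats::rnorm(d, 0, sd_vec)
      lp_prop <- loglik_given_z(prop, mats, es, z, spec, Dmat()) +
        sum(stats::dnorm(prop, 0, control$prior_sd, log = TRUE))
      n_try <- n_try + 1L
      if (log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; n_acc <- n_acc + 1L
      }
      if (it <= control$n_burn && it %% 50 == 0)
        scale <- scale * exp(n_acc / n_try - 0.234)

      if (it > control$n_burn) {
        k <- it - control$n_burn
        draws[k, ] <- theta
        dev[k] <- -2 * obs_loglik_given_z(inv_logit(drop(
          mats$X$p %*% split_params(theta, mats)$p)), es, z)
        qsum <- qsum + z * matrix(inv_logit(drop(
          mats$X$p %*% split_params(theta, mats)$p)), n, Tn)
        qn <- qn + 1L
        if (k %% keep_z == 0) z_store[[length(z_store) + 1L]] <- z
      }
    }
    chains[[ch]] <- draws
    deviance <- c(deviance, dev)
    acc_all <- c(acc_all, n_acc / n_try)
  }
  z_draws <- array(0L, c(length(z_store), n, Tn))
  for (j in seq_along(z_store)) z_draws[j, , ] <- z_store[[j]]
  list(chains = chains, deviance = deviance, accept_rate = mean(acc_all),
       z_draws = z_draws, qbar = qsum / qn)
}

#' Maximum-likelihood fit of a marginalizable occupancy model
#'
#' Direct optimization of the exact marginal log-likelihood (BFGS, several
#' jittered starts). Serves as a frequentist cross-check of the MCMC engine.
#'
#' @param spec An [occu_spec()] without auto-covariate.
#' @param history A `detection_history`.
#' @param stations Station table.
#' @param n_starts Number of jittered starting points.
#' @return List with `par` (logit scale, named), `loglik`, `convergence`.
#' @export
fit_occu_ml <- function(spec, history, stations, n_starts = 3) {
  ids <- dimnames(history$y)[[1]]
  stn <- stations[match(ids, stations$id), , drop = FALSE]
  mats <- build_mats(spec, stn, single_season = dim(history$y)[2] == 1)
  es <- emission_stats(history)
  nll <- function(th) -forward_marginal(th, mats, es)$loglik
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- if (s == 1) rep(0, sum(mats$npar))
            else stats::rnorm(sum(mats$npar), 0, 0.7)
    opt <- tryCatch(stats::optim(init, nll, method = "BFGS",
                                 control = list(maxit = 500)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stopf("optimization failed")
  list(par = stats::setNames(best$par, mats$par_names),
       loglik = -best$value, convergence = best$convergence)
}
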