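#' @export
print.occufit <- function(x, ...) {
  cat(sprintf("Bayesian occupancy model fit (%s engine)\n", x$engine))
  print(x$spec)
  d <- dim(x$history$y)
  cat(sprintf("Data: %d sites x %d season(s) x %d secondary periods\n",
              d[1], d[2], d[3]))
  cat(sprintf("MCMC: %d chains x %d kept draws; acceptance %.2f; max R-hat %.3f%s\n",
              x$control$n_chains, x$control$n_iter, x$accept_rate,
              max(x$rhat, na.rm = TRUE),
              if (x$converged) "" else "  ** NOT CONVERGED **"))
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.occufit <- function(object, ...) colMeans(object$samples)

#' @export
summary.occufit <- function(object, ...) {
  qs <- t(apply(object$samples, 2, stats::quantile,
                c(0.025, 0.5, 0.975)))
  tab <- data.frame(mean = colMeans(object$samples),
                    sd = apply(object$samples, 2, stats::sd),
                    lower = qs[, 1], median = qs[, 2], upper = qs[, 3],
                    rhat = object$rhat)
  ic <- dic(object)
  structure(list(coefficients = tab, dic = ic,
                 pao = pao(object), converged = object$converged,
                 engine = object$engine),
            class = "summary.occufit")
}

#' @export
print.summary.occufit <- function(x, ...) {
  cat("Posterior summary (logit-scale coefficients):\n")
  print(round(x$coefficients, 3))
  cat(sprintf("\nDIC %.1f (pD %.1f, mean deviance %.1f; %s scale)\n",
              x$dic$dic, x$dic$pd, x$dic$mean_deviance, x$dic$scale))
  cat("\nProportion of sites occupied (posterior mean [95% CrI]):\n")
  for (i in seq_len(nrow(x$pao)))
    cat(sprintf("  %-12s %.3f [%.3f, %.3f]\n", x$pao$season[i],
                x$pao$mean[i], x$pao$lower[i], x$pao$upper[i]))
  if (!x$converged) cat("\nWarning: some R-hat values exceed the threshold\n")
  invisible(x)
}

#' Predict occupancy or detection probabilities per site
#'
#' Posterior mean (and credible interval) of a parameter's probability for
#' each station, at the fitted covariate values.
#'
#' @param object An `occufit`.
#' @param parameter One of `"psi1"`, `"gamma"`, `"epsilon"`, `"p"`.
#' @param ... Unused.
#' @return Data frame `id`, `mean`, `lower`, `upper`.
#' @export
predict.occufit <- function(object, parameter = "psi1", ...) {
  if (object$mats$npar[[parameter]] == 0)
    stopf("%s not estimated in this fit", parameter)
  has_auto <- parameter %in% object$spec$auto
  X <- object$mats$X[[parameter]]
  cols <- paste(parameter, c(colnames(X), if (has_auto) "auto"), sep = ".")
  beta <- object$samples[, cols, drop = FALSE]
  if (has_auto) X <- cbind(X, auto = 0)
  pr <- inv_logit(X %*% t(beta))
  data.frame(id = object$stations$id, mean = rowMeans(pr),
             lower = apply(pr, 1, stats::quantile, 0.025),
             upper = apply(pr, 1, stats::quantile, 0.975))
}

#' Posterior-predictive simulation from a fitted occupancy model
#'
#' Draws new latent states and detection histories from the fitted model,
#' one parameter draw per simulation.
#'
#' @param object An `occufit`.
#' @param nsim Number of simulated histories.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return List of `detection_history` objects (length `nsim`).
#' @export
simulate.occufit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  es <- emission_stats(object$history)
  idx <- sample.int(nrow(object$samples), nsim, replace = TRUE)
  lapply(idx, function(j) {
    pf <- prob_fields(object$samples[j, ], object$mats)
    n <- es$n; Tn <- es$T
    z <- matrix(0L, n, Tn)
    z[, 1] <- stats::rbinom(n, 1, pf$psi1)
    if (Tn > 1) for (t in 2:Tn) {
      pr <- z[, t - 1] * (1 - pf$epsilon) + (1 - z[, t - 1]) * pf$gamma
      z[, t] <- stats::rbinom(n, 1, pr)
    }
    y <- object$history$y
    for (t in seq_len(Tn)) for (k in seq_len(dim(y)[3])) {
      obs <- !is.na(y[, t, k])
      y[obs, t, k] <- stats::rbinom(sum(obs), 1, z[obs, t] * pf$p[obs])
    }
    structure(list(y = y, effort = object$history$effort,
                   design = object$history$design),
              class = "detection_history")
  })
}

#' Trace and density plots for an occupancy fit
#'
#' @param x An `occufit`.
#' @param parameters Coefficient names to plot (default: first four).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.occufit <- function(x, parameters = NULL, ...) {
  nm <- parameters %||% utils::head(colnames(x$samples), 4)
  old <- graphics::par(mfrow = c(length(nm), 2), mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (p in nm) {
    traces <- sapply(x$chains, function(ch) ch[, match(p, colnames(x$samples))])
    graphics::matplot(traces, type = "l", lty = 1, ylab = p, xlab = "", ...)
    d <- stats::density(x$samples[, p])
    graphics::plot(d, main = "", xlab = p)
  }
  invisible(x)
}
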