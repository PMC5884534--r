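#' Deviance Information Criterion
#'
#' `pD = mean(deviance) - deviance(at posterior means)` (the Spiegelhalter
#' plug-in definition, matching the JAGS convention) and
#' `DIC = mean(deviance) + pD`. For marginalizable fits the deviance is on
#' the exact marginal-likelihood scale; for auto-covariate (latent-state)
#' fits it is conditional on the latent states, so DICs across the two
#' classes are not strictly comparable — compare like with like.
#'
#' @param fit An `occufit`, or any list carrying numeric `deviance` draws and
#'   a scalar `deviance_at_mean`.
#' @param ... Unused.
#' @return List with `dic`, `pd`, `mean_deviance`, and `scale`
#'   (`"marginal"` or `"conditional"`).
#' @export
dic <- function(fit, ...) UseMethod("dic")

#' @export
dic.occufit <- function(fit, ...) {
  out <- dic_from_deviance(fit$deviance, fit$deviance_at_mean)
  out$scale <- if (fit$engine == "marginal") "marginal" else "conditional"
  out
}

#' @export
dic.default <- function(fit, ...) {
  if (is.null(fit[["deviance"]]) || is.null(fit[["deviance_at_mean"]]))
    stopf("need deviance draws and deviance_at_mean")
  dic_from_deviance(fit[["deviance"]], fit[["deviance_at_mean"]])
}

dic_from_deviance <- function(deviance, deviance_at_mean) {
  if (!length(deviance)) stopf("no deviance draws")
  dbar <- mean(deviance)
  pd <- dbar - deviance_at_mean
  list(dic = dbar + pd, pd = pd, mean_deviance = dbar)
}
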