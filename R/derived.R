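#' Proportion of area (sites) occupied
#'
#' Finite-sample PAO from the posterior draws of the latent states:
#' for each draw, the fraction of sites with `z = 1` in a season, optionally
#' restricted to a site subset (e.g. coastal vs inland habitats).
#'
#' @param fit An `occufit`.
#' @param season Season label or index, or `NULL` for all seasons.
#' @param sites Optional site ids or indices to restrict to.
#' @return Data frame: `season`, `mean`, `lower`, `upper` (95% credible
#'   interval), `n_sites`.
#' @export
pao <- function(fit, season = NULL, sites = NULL) {
  labs <- dimnames(fit$history$y)[[2]]
  ti <- if (is.null(season)) seq_along(labs)
        else if (is.character(season)) match(season, labs)
        else season
  if (anyNA(ti) || any(ti < 1) || any(ti > length(labs)))
    stopf("season not present in fit")
  ids <- dimnames(fit$history$y)[[1]]
  si <- if (is.null(sites)) seq_along(ids)
        else if (is.character(sites)) match(sites, ids)
        else sites
  if (anyNA(si)) stopf("unknown site id in subset")
  out <- lapply(ti, function(t) {
    draws <- apply(fit$z_draws[, si, t, drop = FALSE], 1, mean)
    data.frame(season = labs[t], mean = mean(draws),
               lower = unname(stats::quantile(draws, 0.025)),
               upper = unname(stats::quantile(draws, 0.975)),
               n_sites = length(si), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Covariate response curve with credible band
#'
#' Inverse-logit of a parameter's linear predictor over a grid of one raw
#' covariate (back-transformed through the stored standardization), with all
#' other covariates held at their mean (0 on the standardized scale) and any
#' auto-covariate at 0.
#'
#' @param fit An `occufit`.
#' @param parameter One of `"psi1"`, `"gamma"`, `"epsilon"`, `"p"`.
#' @param covariate Covariate name present in that parameter's formula.
#' @param grid Number of grid points, or a numeric vector of raw values.
#' @return Data frame: `covariate` (raw scale), `mean`, `lower`, `upper`.
#' @export
response_curve <- function(fit, parameter, covariate, grid = 100) {
  terms <- spec_terms(fit$spec, parameter)
  base <- gsub("^I\\(|\\^2\\)$", "", terms)
  if (!covariate %in% base)
    stopf("covariate '%s' is not in the %s structure", covariate, parameter)
  if (parameter %in% c("gamma", "epsilon") && fit$mats$npar[[parameter]] == 0)
    stopf("%s not estimated for single-season fits", parameter)
  raw <- if (length(grid) > 1) grid
         else seq(min(fit$stations[[covariate]]),
                  max(fit$stations[[covariate]]), length.out = grid)
  sc_i <- match(covariate, fit$scaling$covariate)
  std <- if (!is.na(sc_i)) (raw - fit$scaling$mean[sc_i]) / fit$scaling$sd[sc_i]
         else raw
  # linear predictor columns of this parameter only
  Xnames <- colnames(fit$mats$X[[parameter]])
  has_auto <- parameter %in% fit$spec$auto
  cols <- paste(parameter, c(Xnames, if (has_auto) "auto"), sep = ".")
  beta <- fit$samples[, cols, drop = FALSE]
  Xg <- matrix(0, length(std), length(cols))
  colnames(Xg) <- cols
  Xg[, paste0(parameter, ".(Intercept)")] <- 1
  lin_col <- paste0(parameter, ".", covariate)
  if (lin_col %in% cols) Xg[, lin_col] <- std
  quad_col <- paste0(parameter, ".I(", covariate, "^2)")
  if (quad_col %in% cols) Xg[, quad_col] <- std^2
  eta <- Xg %*% t(beta)
  pr <- inv_logit(eta)
  data.frame(covariate = raw,
             mean = rowMeans(pr),
             lower = apply(pr, 1, stats::quantile, 0.025),
             upper = apply(pr, 1, stats::quantile, 0.975))
}
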