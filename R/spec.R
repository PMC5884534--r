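#' Specify an occupancy model structure
#'
#' One-sided formulas give the covariate structure (logit link) of each
#' probability parameter: initial occupancy `psi1`, colonization `gamma`,
#' extinction `epsilon` and detection `p`. Quadratic terms are written
#' `~ x + I(x^2)`. The spatiotemporal auto-covariate may additionally enter
#' the dynamics (`gamma` and/or `epsilon` only).
#'
#' @param psi1,gamma,epsilon,p One-sided formulas (default intercept-only).
#' @param auto Character vector, subset of `c("gamma", "epsilon")`: which
#'   dynamic parameters include the auto-covariate.
#' @param flagged Optional collinearity table from [collinearity_screen()];
#'   a specification combining a flagged pair is refused unless
#'   `allow_flagged = TRUE`.
#' @param allow_flagged Override the collinearity refusal.
#' @return An `occu_spec` object.
#' @export
occu_spec <- function(psi1 = ~1, gamma = ~1, epsilon = ~1, p = ~1,
                      auto = character(0), flagged = NULL,
                      allow_flagged = FALSE) {
  if (length(auto) && !all(auto %in% c("gamma", "epsilon")))
    stopf("auto-covariate allowed only on gamma and epsilon")
  spec <- structure(list(psi1 = psi1, gamma = gamma, epsilon = epsilon, p = p,
                         auto = auto),
                    class = "occu_spec")
  if (!is.null(flagged) && !allow_flagged) {
    for (par in c("psi1", "gamma", "epsilon", "p")) {
      tl <- spec_terms(spec, par)
      if (uses_flagged_pair(tl, flagged))
        stopf("%s combines a collinearity-flagged covariate pair; use allow_flagged = TRUE to override", par)
    }
  }
  spec
}

# Term labels of one parameter's formula.
spec_terms <- function(spec, par) {
  attr(stats::terms(spec[[par]]), "term.labels")
}

#' @export
print.occu_spec <- function(x, ...) {
  fm <- function(f) paste(deparse(f), collapse = "")
  cat("Occupancy model specification (logit link):\n")
  cat(sprintf("  psi1:    %s\n  gamma:   %s%s\n  epsilon: %s%s\n  p:       %s\n",
              fm(x$psi1),
              fm(x$gamma), if ("gamma" %in% x$auto) " + auto" else "",
              fm(x$epsilon), if ("epsilon" %in% x$auto) " + auto" else "",
              fm(x$p)))
  invisible(x)
}

# Design matrices for each parameter on the (already standardized) station
# table, plus the coefficient layout. Auto-covariate columns are appended at
# fit time, not here.
spec_matrices <- function(spec, stations) {
  mk <- function(f) stats::model.matrix(f, stations)
  X <- list(psi1 = mk(spec$psi1), gamma = mk(spec$gamma),
            epsilon = mk(spec$epsilon), p = mk(spec$p))
  npar <- vapply(X, ncol, integer(1))
  npar["gamma"] <- npar[["gamma"]] + ("gamma" %in% spec$auto)
  npar["epsilon"] <- npar[["epsilon"]] + ("epsilon" %in% spec$auto)
  names_of <- function(par) {
    nm <- colnames(X[[par]])
    if (par %in% c("gamma", "epsilon") && par %in% spec$auto) nm <- c(nm, "auto")
    paste(par, nm, sep = ".")
  }
  list(X = X, npar = npar,
       par_names = c(names_of("psi1"), names_of("gamma"),
                     names_of("epsilon"), names_of("p")),
       offsets = cumsum(c(0, npar))[1:4])
}

# Split a flat coefficient vector into per-parameter pieces.
split_params <- function(theta, mats) {
  off <- mats$offsets
  np <- mats$npar
  list(psi1 = theta[off[1] + seq_len(np[1])],
       gamma = theta[off[2] + seq_len(np[2])],
       epsilon = theta[off[3] + seq_len(np[3])],
       p = theta[off[4] + seq_len(np[4])])
}
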