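#' Gelman-Rubin convergence diagnostic (split R-hat)
#'
#' Computes the potential scale reduction factor per parameter from two or
#' more chains, each chain split in half (so within-chain drift also inflates
#' the statistic). Values near 1 indicate convergence; 1.1 is the customary
#' flagging threshold.
#'
#' @param chains A list of equal-size matrices (iterations x parameters), or
#'   a single matrix list for one parameter per column.
#' @return Named numeric vector of R-hat values (one per parameter).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- list(chains)
  if (length(chains) < 2 && nrow(chains[[1]]) < 4)
    stopf("need at least two chains (or one chain long enough to split)")
  if (length(chains) < 2)
    stopf("need at least two chains")
  iters <- vapply(chains, nrow, integer(1))
  if (length(unique(iters)) != 1) stopf("chains must have equal lengths")
  half <- iters[1] %/% 2
  split_chains <- list()
  for (ch in chains) {
    split_chains[[length(split_chains) + 1]] <- ch[seq_len(half), , drop = FALSE]
    split_chains[[length(split_chains) + 1]] <- ch[half + seq_len(half), , drop = FALSE]
  }
  m <- length(split_chains)
  n <- half
  npar <- ncol(chains[[1]])
  rhat <- numeric(npar)
  for (j in seq_len(npar)) {
    means <- vapply(split_chains, function(ch) mean(ch[, j]), numeric(1))
    vars <- vapply(split_chains, function(ch) stats::var(ch[, j]), numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (!is.finite(W) || W <= 1e-300) {
      rhat[j] <- if (is.finite(B) && B <= 1e-300) 1 else Inf
    } else {
      rhat[j] <- sqrt(((n - 1) / n * W + B / n) / W)
    }
  }
  names(rhat) <- colnames(chains[[1]]) %||% paste0("par", seq_len(npar))
  rhat
}
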