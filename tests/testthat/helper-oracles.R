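# Independent oracles and fixture builders used across the test files.

# Brute-force dynamic-occupancy likelihood: enumerate every latent-state
# configuration z in {0,1}^(n x T) and sum the joint probability. Written
# directly from the model's defining equations, independent of the package's
# forward recursion.
brute_force_loglik <- function(psi1, gamma, epsilon, p, y) {
  n <- dim(y)[1]; Tn <- dim(y)[2]; K <- dim(y)[3]
  psi1 <- rep_len(psi1, n); p <- rep_len(p, n)
  gamma <- rep_len(gamma, n); epsilon <- rep_len(epsilon, n)
  total <- 0
  n_conf <- 2^(n * Tn)
  for (conf in 0:(n_conf - 1)) {
    bits <- as.integer(intToBits(conf))[seq_len(n * Tn)]
    z <- matrix(bits, n, Tn)
    pr <- 1
    for (i in seq_len(n)) {
      pr <- pr * ifelse(z[i, 1] == 1, psi1[i], 1 - psi1[i])
      if (Tn > 1) for (t in 2:Tn) {
        occ <- z[i, t - 1] * (1 - epsilon[i]) + (1 - z[i, t - 1]) * gamma[i]
        pr <- pr * ifelse(z[i, t] == 1, occ, 1 - occ)
      }
      for (t in seq_len(Tn)) for (k in seq_len(K)) {
        if (is.na(y[i, t, k])) next
        q <- z[i, t] * p[i]
        pr <- pr * ifelse(y[i, t, k] == 1, q, 1 - q)
      }
      if (pr == 0) break
    }
    total <- total + pr
  }
  log(total)
}

# Minimal station table with n rows (ids s1..sn), covariates filled with
# plausible values; deterministic given seed.
toy_stations <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    id = paste0("s", seq_len(n)),
    x = runif(n, 0, 5000), y = runif(n, 0, 5000),
    habitat = sample(c("coast_shrubland", "forest", "meadow"), n, TRUE),
    elevation = runif(n, 0, 300), slope = runif(n, 0, 25),
    dist_coast = runif(n, 0, 3000), dist_any_water = runif(n, 0, 800),
    dist_freshwater = runif(n, 0, 900), ground_cover = runif(n, 5, 95),
    stringsAsFactors = FALSE)
}

# Design with n stations, Tn seasons, K secondary periods of len days.
toy_design <- function(station_ids, Tn = 1, K = 4, len = 5,
                       inactive = list()) {
  starts <- as.Date("2014-02-10") + (seq_len(Tn) - 1) * 120
  study_design(station_ids,
               data.frame(label = paste0("t", seq_len(Tn)),
                          start = starts, n_secondary = K,
                          secondary_len = len, stringsAsFactors = FALSE),
               inactive = inactive)
}

# Detection history carrying a given y array (site x season x K).
history_from_y <- function(y, stations = NULL, inactive_ok = TRUE) {
  n <- dim(y)[1]; Tn <- dim(y)[2]; K <- dim(y)[3]
  ids <- paste0("s", seq_len(n))
  des <- toy_design(ids, Tn = Tn, K = K)
  dimnames(y) <- list(ids, des$seasons$label, paste0("k", seq_len(K)))
  # effort mask implied by missingness
  des$active[] <- !apply(is.na(y), c(1, 2), all)
  structure(list(y = y, effort = season_effort(des), design = des),
            class = "detection_history")
}

# Random toy instance for the likelihood oracle.
random_toy <- function(seed) {
  set.seed(seed)
  n <- sample(1:4, 1); Tn <- sample(1:3, 1); K <- 4
  y <- array(rbinom(n * Tn * K, 1, 0.4), c(n, Tn, K))
  if (runif(1) < 0.5) y[sample(length(y), max(1, length(y) %/% 5))] <- NA
  # keep at least one observation per site-season observed or all-missing
  list(y = y, n = n, Tn = Tn, K = K,
       psi1 = runif(1, 0.2, 0.8), gamma = runif(1, 0.1, 0.6),
       epsilon = runif(1, 0.1, 0.6), p = runif(1, 0.2, 0.8))
}

# Events data frame helper.
events_df <- function(station_id, times) {
  data.frame(station_id = station_id,
             timestamp = as.POSIXct(times, tz = "UTC"),
             stringsAsFactors = FALSE)
}

quiet_fit <- function(...) suppressWarnings(fit_occu(...))
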