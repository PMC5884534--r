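# Internal helpers shared across the package.

HABITATS <- c("coast_shrubland", "forest", "meadow")

`%||%` <- function(a, b) if (is.null(a)) b else a

logit <- stats::qlogis
inv_logit <- stats::plogis

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Hours on the 24-h circle -> radians and back.
hours_to_rad <- function(h) h / 24 * 2 * pi
rad_to_hours <- function(r) ((r %% (2 * pi)) / (2 * pi) * 24) %% 24

# Circular mean of clock times given in decimal hours; NA if no resultant.
circular_mean_hours <- function(h) {
  th <- hours_to_rad(h)
  out <- rad_to_hours(atan2(mean(sin(th)), mean(cos(th))))
  if (out > 24 - 1e-9) 0 else out
}

# Parse "HH:MM[:SS]" clock strings to decimal hours.
parse_clock <- function(x) {
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (any(is.na(p)) || length(p) < 2L || length(p) > 3L)
      stopf("malformed clock time")
    p[1] + p[2] / 60 + if (length(p) == 3L) p[3] / 3600 else 0
  }, numeric(1))
}

format_clock <- function(h) {
  h <- h %% 24
  sprintf("%02d:%02d", floor(h), round((h - floor(h)) * 60) %% 60)
}

# Derive a stream-specific 31-bit seed from a base seed (double arithmetic:
# products stay below 2^53, the result below 2^31).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 7919) %%
               2147483647)
}

# Draw n values from a zero-truncated geometric distribution (support >= 1).
rgeom_pos <- function(n, prob) 1L + stats::rgeom(n, prob)
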