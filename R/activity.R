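#' Seasonal mean sun times
#'
#' Circular means of daily sunrise and sunset clock times over the days a
#' season's cameras were operative (robust to times straddling midnight).
#'
#' @param sun_table Data frame `date, sunrise, sunset` (`HH:MM` strings or
#'   decimal hours).
#' @param dates Dates to average over (the operative days); default all rows.
#' @return List with `sunrise` and `sunset` in decimal hours.
#' @export
season_sun_times <- function(sun_table, dates = NULL) {
  tab <- sun_table
  if (!is.null(dates)) {
    tab <- tab[as.Date(tab$date) %in% as.Date(dates), , drop = FALSE]
    if (nrow(tab) == 0) stopf("sun table does not cover the requested days")
  }
  if (nrow(tab) == 0) stopf("empty sun table")
  to_hours <- function(x) if (is.numeric(x)) x else parse_clock(x)
  list(sunrise = circular_mean_hours(to_hours(tab$sunrise)),
       sunset = circular_mean_hours(to_hours(tab$sunset)))
}

#' Partition the 24-h day into dawn/day/dusk/night
#'
#' Dawn is the two hours either side of sunrise, dusk the two hours either
#' side of sunset, day the span between dawn and dusk, and night the
#' remainder; the four half-open intervals tile the circle and availabilities
#' (interval length / 24) sum to 1, with dawn and dusk each exactly 4 h.
#'
#' @param sunrise,sunset Clock times in decimal hours.
#' @return A `period_partition`: list with `intervals` (named list of
#'   `c(start, end)` in hours, end possibly wrapped past 24) and
#'   `availability` (named, sums to 1).
#' @export
diel_partition <- function(sunrise, sunset) {
  span <- (sunset - sunrise) %% 24
  if (span <= 4)
    stopf("day interval empty: sunset - sunrise = %.2f h <= 4 h", span)
  if (span >= 20)
    stopf("night interval empty: sunset - sunrise = %.2f h >= 20 h", span)
  ints <- list(dawn = c(sunrise - 2, sunrise + 2),
               day = c(sunrise + 2, sunset - 2),
               dusk = c(sunset - 2, sunset + 2),
               night = c(sunset + 2, sunrise - 2 + 24))
  ints <- lapply(ints, function(iv) iv %% 24)
  lens <- vapply(ints, function(iv) (iv[2] - iv[1]) %% 24, numeric(1))
  structure(list(sunrise = sunrise %% 24, sunset = sunset %% 24,
                 intervals = ints, availability = lens / 24),
            class = "period_partition")
}

#' @export
print.period_partition <- function(x, ...) {
  cat(sprintf("Diel partition (sunrise %s, sunset %s):\n",
              format_clock(x$sunrise), format_clock(x$sunset)))
  for (p in names(x$intervals))
    cat(sprintf("  %-6s [%s, %s)  availability %.3f\n", p,
                format_clock(x$intervals[[p]][1]),
                format_clock(x$intervals[[p]][2]), x$availability[[p]]))
  invisible(x)
}

# Which period a clock time (decimal hours) belongs to.
period_of <- function(hours, partition) {
  h <- hours %% 24
  out <- character(length(h))
  for (p in names(partition$intervals)) {
    iv <- partition$intervals[[p]]
    inside <- if (iv[1] <= iv[2]) h >= iv[1] & h < iv[2]
              else h >= iv[1] | h < iv[2]
    out[inside] <- p
  }
  factor(out, levels = names(partition$intervals))
}

#' Circular kernel density estimate of diel activity
#'
#' Von Mises kernel density on the 24-h clock:
#' `f(t) = (1/n) sum_j K_kappa(t - t_j)`, evaluated on a regular grid and
#' normalized to integrate to 1 over the circle. `kappa = "auto"` chooses the
#' concentration by maximizing the leave-one-out cross-validated
#' log-likelihood over a log-spaced grid, times `adjust`.
#'
#' @param times_hours Detection clock times in decimal hours (>= 2 distinct).
#' @param kappa Kernel concentration (> 0) or `"auto"`.
#' @param grid_size Number of evaluation points (default 512).
#' @param adjust Multiplier on the auto-chosen concentration (default 1;
#'   larger = less smoothing).
#' @return An `activity_kde`: list with `grid` (hours), `density` (per hour),
#'   `kappa`, `n`, `times`.
#' @export
circular_kde <- function(times_hours, kappa = "auto", grid_size = 512,
                         adjust = 1) {
  times_hours <- times_hours %% 24
  if (length(times_hours) < 2 || length(unique(times_hours)) < 2)
    stopf("need at least 2 distinct times")
  th <- hours_to_rad(times_hours)
  if (identical(kappa, "auto")) kappa <- cv_kappa(th) * adjust
  if (!is.numeric(kappa) || kappa <= 0) stopf("kappa must be > 0 or 'auto'")
  grid <- seq(0, 24, length.out = grid_size + 1)[-(grid_size + 1)]
  gr <- hours_to_rad(grid)
  dens_rad <- vapply(gr, function(g)
    mean(exp(kappa * cos(g - th))) / (2 * pi * besselI(kappa, 0,
                                                      expon.scaled = TRUE) *
                                        exp(kappa)),
    numeric(1))
  dens <- dens_rad * 2 * pi / 24  # per-hour density on [0, 24)
  # renormalize the trapezoid integral on the circle to exactly 1
  dens <- dens / (sum(dens) * 24 / grid_size)
  structure(list(grid = grid, density = dens, kappa = kappa,
                 n = length(times_hours), times = times_hours),
            class = "activity_kde")
}

# Leave-one-out cross-validated concentration for the von Mises kernel.
cv_kappa <- function(th) {
  n <- length(th)
  dmat <- outer(th, th, function(a, b) cos(a - b))
  grid <- exp(seq(log(0.5), log(150), length.out = 40))
  score <- vapply(grid, function(k) {
    km <- exp(k * dmat)
    diag(km) <- 0
    fi <- rowSums(km) / ((n - 1) * 2 * pi * besselI(k, 0,
                                                   expon.scaled = TRUE) *
                           exp(k))
    sum(log(pmax(fi, 1e-300)))
  }, numeric(1))
  grid[which.max(score)]
}

#' @export
print.activity_kde <- function(x, ...) {
  cat(sprintf("Circular activity KDE: n = %d, kappa = %.2f, mode at %s\n",
              x$n, x$kappa, format_clock(x$grid[which.max(x$density)])))
  invisible(x)
}

#' @export
plot.activity_kde <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l", xlab = "Hour of day",
                 ylab = "Density", xaxs = "i", ...)
  graphics::rug(x$times)
  invisible(x)
}

#' Density mass per diel period
#'
#' Numeric (trapezoid) integral of the activity density over each partition
#' interval; the four masses sum to 1 up to integration error.
#'
#' @param kde An `activity_kde`.
#' @param partition A `period_partition`.
#' @return Named numeric vector of proportions (dawn, day, dusk, night).
#' @export
period_mass <- function(kde, partition) {
  per <- period_of(kde$grid, partition)
  step <- 24 / length(kde$grid)
  mass <- vapply(names(partition$intervals), function(p)
    sum(kde$density[per == p]) * step, numeric(1))
  mass / sum(mass)
}

#' Design-I selection ratios with Bonferroni simultaneous intervals
#'
#' For each diel period, the selection ratio `w_i = o_i / pi_i` compares the
#' proportion of use `o_i` with the proportion of time available `pi_i`;
#' `w > 1` indicates selection and `w < 1` avoidance. Standard errors follow
#' the design-I (population-level) formula
#' `SE(w_i) = sqrt(o_i (1 - o_i) / (n pi_i^2))` and the simultaneous
#' intervals use the Bonferroni quantile `z[1 - alpha/(2 I)]` with `I` the
#' number of periods. A period is classified `selected` if the lower bound
#' exceeds 1, `avoided` if the upper bound is below 1, `as_expected`
#' otherwise. Lower bounds are truncated at 0.
#'
#' @param use Named proportions of use (sums to 1), e.g. KDE period masses or
#'   raw detection proportions.
#' @param availability Named availability proportions (sums to 1).
#' @param n Number of independent detections behind `use`.
#' @param alpha Simultaneous error rate (default 0.05).
#' @return A `selection_ratios` data frame: `period, use, availability, w,
#'   se, lower, upper, classification` with attribute `n`.
#' @export
selection_ratios <- function(use, availability, n, alpha = 0.05) {
  if (n < 1) stopf("n must be >= 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (any(availability <= 0)) stopf("zero availability for a period")
  if (abs(sum(use) - 1) > 1e-6 || abs(sum(availability) - 1) > 1e-6)
    stopf("use and availability proportions must each sum to 1")
  periods <- names(availability)
  use <- use[periods]
  I <- length(periods)
  w <- use / availability
  se <- sqrt(use * (1 - use) / (n * availability^2))
  zq <- stats::qnorm(1 - alpha / (2 * I))
  lower <- pmax(0, w - zq * se)
  upper <- w + zq * se
  cls <- ifelse(lower > 1, "selected", ifelse(upper < 1, "avoided",
                                              "as_expected"))
  out <- data.frame(period = periods, use = unname(use),
                    availability = unname(availability), w = unname(w),
                    se = unname(se), lower = unname(lower),
                    upper = unname(upper), classification = unname(cls),
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  class(out) <- c("selection_ratios", "data.frame")
  out
}

#' Full diel activity analysis for one season
#'
#' Chains the steps: seasonal mean sun times, diel partition, circular KDE of
#' the detection times, per-period density mass (or raw count proportions)
#' and selection ratios.
#'
#' @param times_hours Independent detection clock times (decimal hours).
#' @param sun_table Daily sun-times table (see [season_sun_times()]).
#' @param dates Operative days for the seasonal mean sun times.
#' @param use One of `"kde"` (period masses of the smoothed density; default)
#'   or `"counts"` (raw per-period detection proportions).
#' @param kappa,grid_size,adjust Passed to [circular_kde()].
#' @param alpha Simultaneous error rate for the Bonferroni intervals.
#' @return An `activity_result`: list with `partition`, `kde`, `mass`,
#'   `ratios`, `n`.
#' @export
activity_analysis <- function(times_hours, sun_table, dates = NULL,
                              use = c("kde", "counts"), kappa = "auto",
                              grid_size = 512, adjust = 1, alpha = 0.05) {
  use <- match.arg(use)
  sun <- season_sun_times(sun_table, dates)
  part <- diel_partition(sun$sunrise, sun$sunset)
  kde <- circular_kde(times_hours, kappa = kappa, grid_size = grid_size,
                      adjust = adjust)
  mass <- period_mass(kde, part)
  props <- if (use == "kde") mass else {
    tab <- table(period_of(times_hours, part))
    as.numeric(tab) / sum(tab)
  }
  names(props) <- names(part$availability)
  ratios <- selection_ratios(props, part$availability,
                             n = length(times_hours), alpha = alpha)
  structure(list(partition = part, kde = kde, mass = mass, ratios = ratios,
                 n = length(times_hours), use = use),
            class = "activity_result")
}

#' @export
print.activity_result <- function(x, ...) {
  print(x$partition)
  print(x$kde)
  cat(sprintf("Selection ratios (n = %d, use = %s):\n", x$n, x$use))
  tab <- x$ratios
  tab[, c("use", "availability", "w", "se", "lower", "upper")] <-
    round(tab[, c("use", "availability", "w", "se", "lower", "upper")], 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
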