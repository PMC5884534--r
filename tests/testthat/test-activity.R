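test_that("seasonal sun times use circular means", {
  tab <- data.frame(date = as.Date("2014-06-01") + 0:1,
                    sunrise = c("06:00", "06:00"), sunset = c("17:00", "17:00"))
  s <- season_sun_times(tab)
  expect_equal(s$sunrise, 6)

  tab2 <- data.frame(date = as.Date("2014-06-01") + 0:1,
                     sunrise = c("05:50", "06:10"), sunset = c("17:00", "17:00"))
  expect_equal(season_sun_times(tab2)$sunrise, 6, tolerance = 1e-9)

  # straddling midnight averages to midnight, not noon
  tab3 <- data.frame(date = as.Date("2014-06-01") + 0:1,
                     sunrise = c("23:50", "00:10"), sunset = c("12:00", "12:00"))
  expect_equal(season_sun_times(tab3)$sunrise, 0, tolerance = 1e-9)

  expect_error(season_sun_times(tab, dates = as.Date("2020-01-01")),
               "cover")
})

test_that("diel partition tiles the circle with 4-h dawn and dusk", {
  p <- diel_partition(6, 18)
  expect_equal(sum(p$availability), 1)
  expect_equal(unname(p$availability),
               c(4, 8, 4, 8) / 24)  # dawn, day, dusk, night
  # boundary membership: 05:59 is dawn (dawn = [04:00, 08:00))
  expect_equal(as.character(dynocc:::period_of(5 + 59 / 60, p)), "dawn")
  expect_equal(as.character(dynocc:::period_of(8, p)), "day")

  # an 8-h sunrise-to-sunset span gives the 4/4/4/12 split
  p2 <- diel_partition(8, 16)
  expect_equal(unname(p2$availability), c(4, 4, 4, 12) / 24)
  expect_equal(unname(p2$availability["night"]), 0.5)

  expect_error(diel_partition(6, 9), "day interval empty")
  expect_error(diel_partition(1, 22), "night interval empty")
})

test_that("circular KDE is a proper density with the right mode", {
  set.seed(1)
  h <- simulate_activity_times(600, list(type = "vonmises", mean_hours = 2,
                                         kappa = 3), seed = 2)
  k <- circular_kde(h, kappa = 10)
  expect_equal(sum(k$density) * 24 / length(k$grid), 1, tolerance = 1e-6)
  expect_true(all(k$density >= 0))
  mode_at <- k$grid[which.max(k$density)]
  expect_lt(min(abs(mode_at - 2), 24 - abs(mode_at - 2)), 1)

  # near-point data: mode pinned at the atom
  k2 <- circular_kde(c(rep(2, 50), 2.001), kappa = 50)
  expect_equal(k2$grid[which.max(k2$density)], 2, tolerance = 0.05)

  expect_error(circular_kde(rep(2, 10)), "distinct")

  # uniform activity flattens out at large n
  hu <- simulate_activity_times(10000, list(type = "uniform"), seed = 3)
  ku <- circular_kde(hu, kappa = 3)
  expect_lt(max(ku$density) - min(ku$density), 0.25 * mean(ku$density))
})

test_that("period masses integrate the density and match availabilities under uniformity", {
  p <- diel_partition(6, 18)
  # perfectly uniform density
  ku <- circular_kde(c(0.0001, 6, 12, 18), kappa = 1e-9)
  m <- period_mass(ku, p)
  expect_equal(sum(m), 1, tolerance = 1e-9)
  expect_equal(unname(m), unname(p$availability), tolerance = 5e-3)

  # concentrated density at 02:00 puts nearly all mass in night
  kc <- circular_kde(rnorm(200, 2, 0.05) %% 24, kappa = 200)
  mc <- period_mass(kc, p)
  expect_gt(mc[["night"]], 0.95)
})

test_that("selection ratios reproduce the hand-computed fixture", {
  o <- c(dawn = 0.5, day = 0.5 / 3, dusk = 0.5 / 3, night = 0.5 / 3)
  pi4 <- c(dawn = 0.25, day = 0.25, dusk = 0.25, night = 0.25)
  sr <- selection_ratios(o, pi4, n = 400)
  expect_equal(sr$w, c(2, 2 / 3, 2 / 3, 2 / 3), tolerance = 1e-12)
  # SE(w1) = sqrt(.5*.5/(400*.0625)) = 0.1; z_{1-.05/8} = 2.4977
  expect_equal(sr$se[1], 0.1, tolerance = 1e-12)
  z <- qnorm(1 - 0.05 / 8)
  expect_equal(sr$lower[1], 2 - z * 0.1, tolerance = 1e-12)
  expect_equal(sr$classification, c("selected", rep("avoided", 3)))

  # identity: o = pi gives w = 1 everywhere, as expected
  sr2 <- selection_ratios(pi4, pi4, n = 400)
  expect_true(all(sr2$w == 1))
  expect_true(all(sr2$classification == "as_expected"))

  # same proportions at n = 4: intervals widen to cover 1
  sr3 <- selection_ratios(o, pi4, n = 4)
  expect_true(all(sr3$classification == "as_expected"))
  expect_true(all(sr3$lower >= 0))

  expect_error(selection_ratios(o, c(dawn = 0, day = .5, dusk = .25,
                                     night = .25), 10),
               "zero availability")
})

test_that("KDE period masses agree with raw proportions up to smoothing", {
  set.seed(9)
  h <- simulate_activity_times(400, list(type = "vm_mix", mean_hours = 1,
                                         kappa = 2, weight = 0.7), seed = 10)
  p <- diel_partition(7, 19)
  raw <- as.numeric(table(dynocc:::period_of(h, p))) / length(h)
  m_smooth <- period_mass(circular_kde(h, kappa = 20), p)
  m_rough <- period_mass(circular_kde(h, kappa = 100), p)
  expect_lt(max(abs(m_rough - raw)), max(abs(m_smooth - raw)) + 0.02)
  expect_lt(max(abs(m_rough - raw)), 0.05)
})

test_that("Bonferroni intervals approach nominal simultaneous coverage", {
  pi4 <- c(dawn = 1 / 6, day = 1 / 3, dusk = 1 / 6, night = 1 / 3)
  coverage_at <- function(n, reps) {
    mean(replicate(reps, {
      counts <- drop(rmultinom(1, n, pi4))
      sr <- selection_ratios(setNames(counts / n, names(pi4)), pi4, n = n)
      all(sr$lower <= 1 & sr$upper >= 1)
    }))
  }
  set.seed(33)
  # the Wald-type standard error undercovers slightly at small n ...
  expect_gte(coverage_at(150, 500), 0.93)
  # ... and the Bonferroni correction is conservative in the large-n regime
  expect_gte(coverage_at(2000, 500), 0.95)
})

test_that("activity_analysis chains the steps for a winter-like season", {
  set.seed(44)
  days <- as.Date("2014-06-20") + 0:19
  sun <- simulate_sun_times(days)
  h <- simulate_activity_times(200, list(type = "vm_mix", mean_hours = 1.5,
                                         kappa = 2, weight = 0.8), seed = 45)
  res <- activity_analysis(h, sun, dates = days, kappa = 30)
  expect_s3_class(res$ratios, "selection_ratios")
  expect_equal(sum(res$mass), 1, tolerance = 1e-6)
  expect_equal(res$ratios$classification[res$ratios$period == "night"],
               "selected")
  expect_equal(res$ratios$classification[res$ratios$period == "day"],
               "avoided")
  # raw-count mode is also available
  res2 <- activity_analysis(h, sun, dates = days, use = "counts", kappa = 30)
  expect_equal(sum(res2$ratios$use), 1, tolerance = 1e-9)
})
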