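test_that("detection files parse, reject malformed timestamps and unknown stations", {
  stn <- toy_stations(3)
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("station_id,timestamp",
               "s1,2014-02-12T04:30",
               "s2,2014-02-12 23:59",
               "s1,2014-02-13T00:00"), f)
  ev <- read_detections(f, stn)
  expect_equal(nrow(ev), 3)
  expect_s3_class(ev$timestamp, "POSIXct")
  expect_true(all(diff(order(ev$timestamp[c(1, 3)])) > 0))

  writeLines("station_id,timestamp", f)
  expect_equal(nrow(read_detections(f, stn)), 0)

  writeLines(c("station_id,timestamp", "s1,2014-13-01T00:00"), f)
  expect_error(read_detections(f, stn), "row 1")

  writeLines(c("station_id,timestamp", "s1,2014-02-12T04:30",
               "zz,2014-02-12T05:30"), f)
  expect_error(read_detections(f, stn), "unknown station.*row 2")
})

test_that("independence filter keeps events by the greedy >gap rule", {
  ev <- events_df("s1", c("2014-02-12 00:00", "2014-02-12 00:30",
                          "2014-02-12 01:30"))
  kept <- filter_independent(ev, 60)
  expect_equal(format(kept$timestamp, "%H:%M"), c("00:00", "01:30"))

  # exactly at the gap is not strictly greater: discarded
  ev2 <- events_df("s1", c("2014-02-12 00:00", "2014-02-12 01:00"))
  expect_equal(nrow(filter_independent(ev2, 60)), 1)

  # stations never interact
  ev3 <- events_df(c("s1", "s2"),
                   c("2014-02-12 00:00", "2014-02-12 00:10"))
  expect_equal(nrow(filter_independent(ev3, 60)), 2)
})

test_that("independence filter is idempotent on random event sets", {
  set.seed(42)
  for (rep in 1:5) {
    ev <- events_df(sample(paste0("s", 1:3), 40, TRUE),
                    as.POSIXct("2014-02-12", tz = "UTC") +
                      sort(sample.int(72 * 3600, 40)))
    once <- filter_independent(ev, 60)
    twice <- filter_independent(once, 60)
    expect_equal(twice, once)
  }
})

test_that("history construction places events in half-open 5-day periods", {
  stn <- toy_stations(2)
  des <- toy_design(stn$id[1:2], Tn = 1)
  # day 7 of the season (start + 7) falls in period 2 ([5, 10))
  ev <- events_df("s1", "2014-02-17 12:00")
  h <- build_history(ev, des, stn)
  expect_equal(unname(h$y["s1", 1, ]), c(0, 1, 0, 0))
  expect_equal(unname(h$y["s2", 1, ]), c(0, 0, 0, 0))

  # two events in the same period still give a single 1
  ev2 <- events_df(c("s1", "s1"), c("2014-02-17 12:00", "2014-02-18 12:00"))
  h2 <- build_history(ev2, des, stn)
  expect_equal(unname(h2$y["s1", 1, ]), c(0, 1, 0, 0))

  # inactive station-season is all missing
  des3 <- toy_design(stn$id[1:2], Tn = 2, inactive = list(t2 = "s2"))
  h3 <- build_history(ev, des3, stn)
  expect_true(all(is.na(h3$y["s2", "t2", ])))
  expect_true(all(h3$y["s2", "t1", ] == 0))
  expect_equal(h3$effort["s2", "t2"], 0)

  # event outside every window errors
  expect_error(build_history(events_df("s1", "2013-01-01 00:00"), des, stn),
               "outside every season window")
})

test_that("standardization uses the sample sd, stores scaling, and inverts", {
  stn <- toy_stations(2)
  stn$elevation <- c(0, 10)
  out <- standardize_covariates(stn, "elevation")
  expect_equal(out$stations$elevation, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(out$scaling$sd, sd(c(0, 10)))

  # idempotence up to floating error
  again <- standardize_covariates(out$stations, "elevation")
  expect_equal(again$stations$elevation, out$stations$elevation,
               tolerance = 1e-12)

  # round trip through the stored scaling
  stn2 <- toy_stations(40, seed = 3)
  res <- standardize_covariates(stn2, c("elevation", "slope"))
  back <- unstandardize(res$stations$elevation, res$scaling, "elevation")
  expect_equal(back, stn2$elevation, tolerance = 1e-10)

  stn2$slope <- 5
  expect_error(standardize_covariates(stn2, "slope"), "zero variance")
})

test_that("collinearity screen flags monotone pairs and passes independent ones", {
  stn <- toy_stations(1000, seed = 7)
  stn$elevation <- stn$dist_coast * 2 + 5
  fl <- collinearity_screen(stn, c("elevation", "dist_coast"))
  expect_equal(nrow(fl), 1)
  expect_equal(fl$rho, 1)

  stn$elevation <- -stn$dist_coast
  fl2 <- collinearity_screen(stn, c("elevation", "dist_coast"))
  expect_equal(abs(fl2$rho), 1)

  # independent columns at n = 1000 stay unflagged at 0.7
  set.seed(11)
  stn$elevation <- rnorm(1000)
  stn$dist_coast <- runif(1000, 0, 100)
  expect_equal(nrow(collinearity_screen(stn, c("elevation", "dist_coast"))), 0)
})

test_that("capture rate arithmetic matches hand-computed fixtures", {
  expect_equal(capture_rate(4, 200), 2.0)
  expect_equal(capture_rate(0, 200), 0.0)
  expect_equal(round(capture_rate(193, 1802), 2), 10.71)
  expect_error(capture_rate(4, 0), "effort")
})

test_that("distance binning uses half-open 50-m segments and NA for zero effort", {
  stn <- toy_stations(3)
  stn$dist_freshwater <- c(120, 50, 430)
  eff <- c(s1 = 100, s2 = 40, s3 = 0)
  ev <- events_df(c("s1", "s1", "s1", "s2"),
                  sprintf("2014-02-%02d 10:00", 12:15))
  tab <- detection_rate_by_distance(ev, stn, eff)
  b100 <- tab[tab$bin_start == 100, ]
  expect_equal(b100$n_events, 3)
  expect_equal(b100$rate, 3.0)
  # boundary: exactly 50 goes into [50, 100)
  b50 <- tab[tab$bin_start == 50, ]
  expect_equal(b50$n_events, 1)
  expect_equal(b50$rate, 2.5)
  # zero-effort bin: undefined, not zero
  b400 <- tab[tab$bin_start == 400, ]
  expect_true(is.na(b400$rate))
  # effort is conserved across bins
  expect_equal(sum(tab$trap_nights), sum(eff))
  # 3 events / 60 trap nights -> 5.0
  expect_equal(capture_rate(3, 60), 5.0)
})

test_that("histories round-trip through delimited text", {
  stn <- toy_stations(3)
  des <- toy_design(stn$id, Tn = 2, inactive = list(t2 = "s3"))
  ev <- events_df(c("s1", "s2"), c("2014-02-11 10:00", "2014-06-12 22:00"))
  h <- build_history(ev, des, stn)
  f <- withr::local_tempfile(fileext = ".csv")
  write_history(h, f, header = "seed=1")
  df <- read.csv(f, comment.char = "#")
  expect_equal(nrow(df), 6)
  expect_equal(df$k1[df$site == "s1" & df$season == "t1"], 1)
  expect_true(is.na(df$k1[df$site == "s3" & df$season == "t2"]))
})
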