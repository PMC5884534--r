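#' Ground truth for a synthetic camera-trap study
#'
#' Bundles the generating values for a synthetic occupancy study: logit-scale
#' coefficient vectors for initial occupancy, colonization, extinction and
#' detection (named by model term, `(Intercept)` plus covariate names,
#' optionally `I(name^2)` for quadratics), optional auto-covariate
#' coefficients on the dynamics, the neighbour radius, the per-season diel
#' activity mixtures, and the seed. Coefficients are on the standardized
#' covariate scale.
#'
#' Defaults echo the study system the generator emulates: initial occupancy
#' around 0.55--0.6 declining with elevation, detection raised by ground
#' cover and depressed by distance to water, modest turnover
#' (colonization ~0.2, extinction ~0.3) driven by distance to water, no
#' auto-covariate effect, uniform diel activity in summer seasons and
#' night-concentrated activity in winter/spring.
#'
#' @param psi1,gamma,epsilon,p Named coefficient vectors (logit scale).
#' @param auto Named numeric, auto-covariate coefficients for `gamma` and/or
#'   `epsilon` (0 = absent).
#' @param neighbor_radius Neighbour radius in metres for the auto-covariate.
#' @param diel Named list (by season label) of diel mixture specs; see
#'   [simulate_activity_times()].
#' @param event_geom_prob Success probability of the zero-truncated geometric
#'   draw for the number of events in a detected secondary period.
#' @param seed Integer seed recorded with the truth.
#' @return A `synthetic_truth` object.
#' @export
synthetic_truth <- function(
    psi1 = c("(Intercept)" = stats::qlogis(0.58), elevation = -0.6),
    gamma = c("(Intercept)" = stats::qlogis(0.2), dist_any_water = -0.5),
    epsilon = c("(Intercept)" = stats::qlogis(0.3), dist_any_water = 0.5),
    p = c("(Intercept)" = stats::qlogis(0.4), dist_any_water = -0.5,
          ground_cover = 0.5),
    auto = c(gamma = 0, epsilon = 0),
    neighbor_radius = 1500,
    diel = list(
      summer2014 = list(type = "uniform"),
      winter2014 = list(type = "vm_mix", mean_hours = 1.5, kappa = 2,
                        weight = 0.8),
      spring2014 = list(type = "vm_mix", mean_hours = 1.5, kappa = 2.5,
                        weight = 0.85),
      summer2015 = list(type = "uniform")),
    event_geom_prob = 0.5,
    seed = 1L) {
  for (m in names(diel)) {
    w <- diel[[m]]$weight
    if (!is.null(w) && (w < 0 || w > 1)) stopf("mixture weight outside [0,1]")
  }
  structure(list(psi1 = psi1, gamma = gamma, epsilon = epsilon, p = p,
                 auto = auto, neighbor_radius = neighbor_radius, diel = diel,
                 event_geom_prob = event_geom_prob, seed = as.integer(seed)),
            class = "synthetic_truth")
}

#' Simulate a station landscape
#'
#' Places coastal-shrubland stations along a coastline (spacing drawn from the
#' 1363--2782 m range) and inland forest/meadow stations on a jittered grid at
#' ~810 m spacing (720--1053 m range), then draws habitat covariates.
#' Elevation is generated positively correlated with distance to the coast
#' (target Spearman rho ~ 0.87) to reproduce the collinearity situation the
#' covariate screen must catch.
#'
#' @param n_stations Number of stations (default 93).
#' @param habitat_mix Named proportions over
#'   `coast_shrubland`, `forest`, `meadow`; must sum to 1.
#' @param seed Integer seed.
#' @return A validated station table.
#' @export
simulate_landscape <- function(n_stations = 93,
                               habitat_mix = c(coast_shrubland = 20 / 93,
                                               forest = 38 / 93,
                                               meadow = 35 / 93),
                               seed = 1L) {
  if (n_stations < 2) stopf("need at least 2 stations")
  if (abs(sum(habitat_mix) - 1) > 1e-8 || any(habitat_mix < 0))
    stopf("habitat_mix proportions must be nonnegative and sum to 1")
  if (!all(names(habitat_mix) %in% HABITATS))
    stopf("habitat_mix names must be among: %s", paste(HABITATS, collapse = ", "))
  set.seed(as.integer(seed))
  n_coast <- round(n_stations * habitat_mix[["coast_shrubland"]])
  n_forest <- round(n_stations * habitat_mix[["forest"]])
  n_meadow <- n_stations - n_coast - n_forest
  habitat <- c(rep("coast_shrubland", n_coast), rep("forest", n_forest),
               rep("meadow", n_meadow))

  # coastline along y = 0; coastal stations hug it, inland stations sit on a
  # jittered grid starting ~600 m from the shore
  x <- y <- numeric(n_stations)
  if (n_coast > 0) {
    x[seq_len(n_coast)] <- cumsum(stats::runif(n_coast, 1363, 2782))
    y[seq_len(n_coast)] <- stats::runif(n_coast, 0, 60)
  }
  n_inland <- n_stations - n_coast
  if (n_inland > 0) {
    # a coastal strip: the along-shore extent grows with n, the inland depth
    # (hence the distance-to-coast range) stays fixed at five ~810-m rows
    n_rows <- 5L
    gi <- seq_len(n_inland) - 1L
    spacing <- 810
    idx <- n_coast + seq_len(n_inland)
    x[idx] <- (gi %/% n_rows) * spacing + stats::runif(n_inland, -120, 120)
    y[idx] <- 600 + (gi %% n_rows) * spacing + stats::runif(n_inland, -120, 120)
  }

  dist_coast <- y
  # elevation rises with distance from the coast; noise sd tuned so the rank
  # correlation lands near 0.87
  elevation <- pmax(0, 0.08 * dist_coast + stats::rnorm(n_stations, 0, 60))
  slope <- pmin(35, pmax(0, stats::rnorm(n_stations, 10, 6)))
  ground_cover <- pmin(100, pmax(0, ifelse(
    habitat == "forest", stats::rnorm(n_stations, 65, 15),
    ifelse(habitat == "meadow", stats::rnorm(n_stations, 35, 15),
           stats::rnorm(n_stations, 50, 15)))))
  dist_freshwater <- ifelse(
    habitat == "coast_shrubland",
    stats::runif(n_stations, 200, 1500),
    pmin(900, stats::rexp(n_stations, 1 / 260)))
  dist_any_water <- pmin(dist_coast, dist_freshwater)

  validate_stations(data.frame(
    id = sprintf("st%03d", seq_len(n_stations)),
    x = x, y = y, habitat = habitat,
    elevation = elevation, slope = slope, dist_coast = dist_coast,
    dist_any_water = dist_any_water, dist_freshwater = dist_freshwater,
    ground_cover = ground_cover, stringsAsFactors = FALSE))
}

# Linear predictor for a named coefficient vector on a standardized table.
truth_eta <- function(beta, data) {
  terms <- setdiff(names(beta), "(Intercept)")
  X <- if (length(terms))
    stats::model.matrix(stats::reformulate(terms), data)
  else
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  drop(X[, names(beta), drop = FALSE] %*% beta)
}

#' Simulate latent occupancy dynamics and a detection history
#'
#' Draws the latent occupancy states from the two-state Markov chain (initial
#' Bernoulli with probability psi1; transitions by persistence 1 - epsilon and
#' colonization gamma, with the neighbour auto-covariate from the previous
#' season's states entering the dynamics when its coefficient is nonzero),
#' then observations `y(i,t,k) ~ Bern(z(i,t) p(i))`, and finally one or more
#' timestamped events inside each detected secondary period, with clock times
#' drawn from the season's diel mixture.
#'
#' @param truth A [synthetic_truth()].
#' @param stations Station table (raw scale; standardized internally).
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return List with `z` (site x season 0/1 matrix), `history`
#'   (`detection_history`), `events` (data frame), and `psi1`, `gamma`,
#'   `epsilon`, `p` (probability-scale vectors/matrices used).
#' @export
simulate_dynamics <- function(truth, stations, design, seed = truth$seed) {
  set.seed(as.integer(seed))
  ids <- design$station_ids
  stn <- stations[match(ids, stations$id), , drop = FALSE]
  covs <- c("elevation", "slope", "dist_coast", "dist_any_water",
            "dist_freshwater", "ground_cover")
  used <- unique(gsub("^I\\(|\\^2\\)$", "",
                      setdiff(c(names(truth$psi1), names(truth$gamma),
                                names(truth$epsilon), names(truth$p)),
                              "(Intercept)")))
  used <- intersect(covs, used)
  std <- if (length(used)) standardize_covariates(stn, used)$stations else stn

  n <- length(ids)
  Tn <- nrow(design$seasons)
  psi1 <- inv_logit(truth_eta(truth$psi1, std))
  p_site <- inv_logit(truth_eta(truth$p, std))
  eta_g0 <- truth_eta(truth$gamma, std)
  eta_e0 <- truth_eta(truth$epsilon, std)
  use_auto <- any(truth$auto != 0)
  graph <- if (use_auto) build_neighbor_graph(stn, truth$neighbor_radius)

  z <- matrix(0L, n, Tn, dimnames = list(ids, design$seasons$label))
  z[, 1] <- stats::rbinom(n, 1, psi1)
  gam <- eps <- matrix(NA_real_, n, max(Tn - 1, 0))
  if (Tn > 1) for (t in 2:Tn) {
    eta_g <- eta_g0
    eta_e <- eta_e0
    if (use_auto) {
      D <- auto_covariate(z[, t - 1], graph)
      eta_g <- eta_g + truth$auto[["gamma"]] * D
      eta_e <- eta_e + truth$auto[["epsilon"]] * D
    }
    gam[, t - 1] <- inv_logit(eta_g)
    eps[, t - 1] <- inv_logit(eta_e)
    pr <- z[, t - 1] * (1 - eps[, t - 1]) + (1 - z[, t - 1]) * gam[, t - 1]
    z[, t] <- stats::rbinom(n, 1, pr)
  }

  K <- max(design$seasons$n_secondary)
  y <- array(NA_real_, c(n, Tn, K),
             dimnames = list(ids, design$seasons$label, paste0("k", seq_len(K))))
  ev_station <- character(0)
  ev_time <- as.POSIXct(character(0), tz = "UTC")
  for (t in seq_len(Tn)) {
    Kt <- design$seasons$n_secondary[t]
    len <- design$seasons$secondary_len[t]
    mix <- truth$diel[[design$seasons$label[t]]] %||% list(type = "uniform")
    for (i in seq_len(n)) {
      if (!design$active[i, t]) next
      y[i, t, seq_len(Kt)] <- stats::rbinom(Kt, 1, z[i, t] * p_site[i])
      for (k in seq_len(Kt)) {
        if (is.na(y[i, t, k]) || y[i, t, k] == 0) next
        n_ev <- rgeom_pos(1, truth$event_geom_prob)
        day <- sample.int(len, n_ev, replace = TRUE) - 1L
        hrs <- simulate_activity_times(n_ev, mix, seed = NULL)
        start <- deploy_start(design, i, t) + (k - 1) * len
        ev_station <- c(ev_station, rep(ids[i], n_ev))
        ev_time <- c(ev_time, as.POSIXct(start + day, tz = "UTC") + round(hrs * 3600))
      }
    }
  }
  events <- data.frame(station_id = ev_station, timestamp = ev_time,
                       stringsAsFactors = FALSE)
  events <- events[order(events$station_id, events$timestamp), , drop = FALSE]
  rownames(events) <- NULL
  history <- structure(list(y = y, effort = season_effort(design),
                            design = design),
                       class = "detection_history")
  list(z = z, history = history, events = events,
       psi1 = psi1, gamma = gam, epsilon = eps, p = p_site)
}

#' Draw diel activity clock times
#'
#' Samples times on the 24-h circle from a mixture specification:
#' * `list(type = "uniform")` — activity spread evenly over the day
#'   (summer-like);
#' * `list(type = "vonmises", mean_hours, kappa)` — unimodal circular
#'   concentration;
#' * `list(type = "vm_mix", mean_hours, kappa, weight)` — von Mises with
#'   probability `weight`, uniform otherwise (night-concentrated winter-like
#'   activity when `mean_hours` sits mid-night);
#' * `list(type = "point", mean_hours)` — a point mass (degenerate case).
#'
#' @param n Number of draws (>= 0).
#' @param mixture Mixture spec (see above).
#' @param seed Optional integer seed; `NULL` continues the current RNG stream.
#' @return Numeric vector of decimal hours in `[0, 24)`.
#' @export
simulate_activity_times <- function(n, mixture = list(type = "uniform"),
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (n == 0) return(numeric(0))
  switch(mixture$type,
    uniform = stats::runif(n, 0, 24),
    point = rep(mixture$mean_hours %% 24, n),
    vonmises = rad_to_hours(rvonmises(n, hours_to_rad(mixture$mean_hours),
                                      mixture$kappa)),
    vm_mix = {
      from_vm <- stats::runif(n) < mixture$weight
      out <- stats::runif(n, 0, 24)
      if (any(from_vm))
        out[from_vm] <- rad_to_hours(rvonmises(sum(from_vm),
                                               hours_to_rad(mixture$mean_hours),
                                               mixture$kappa))
      out
    },
    stopf("unknown mixture type '%s'", mixture$type))
}

# Best-Fisher (1979) rejection sampler for the von Mises distribution.
rvonmises <- function(n, mu, kappa) {
  if (kappa <= 0) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      zc <- cos(pi * u[1])
      f <- (1 + r * zc) / (r + zc)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
        break
      }
    }
  }
  out
}

#' Synthetic daily sunrise/sunset table
#'
#' Deterministic astronomical approximation (solar declination from day of
#' year, hour angle from latitude) adequate for building seasonal mean
#' sun-time partitions; at the default latitude (55 S) summer days are long
#' and winter days short.
#'
#' @param dates Vector of `Date`s.
#' @param latitude Latitude in degrees (negative south; default -55).
#' @return Data frame `date, sunrise, sunset` with `HH:MM` clock strings.
#' @export
simulate_sun_times <- function(dates, latitude = -55) {
  dates <- as.Date(dates)
  doy <- as.integer(format(dates, "%j"))
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  lat <- latitude * pi / 180
  cosH <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  half_day <- acos(cosH) * 12 / pi
  data.frame(date = dates,
             sunrise = format_clock(12 - half_day),
             sunset = format_clock(12 + half_day),
             stringsAsFactors = FALSE)
}

#' Default synthetic study design
#'
#' Four seasons (two summers, one winter, one spring), four 5-day secondary
#' periods each; in winter only a subset of stations is operative, emulating
#' restricted site access.
#'
#' @param station_ids Station ids.
#' @param n_winter Number of stations operative in winter (default 47 when
#'   there are >= 47 stations, otherwise about half).
#' @param seed Seed for the winter subset draw.
#' @return A `study_design`.
#' @export
default_design <- function(station_ids, n_winter = NULL, seed = 1L) {
  n <- length(station_ids)
  if (is.null(n_winter)) n_winter <- if (n >= 93) 47L else max(1L, n %/% 2)
  seasons <- data.frame(
    label = c("summer2014", "winter2014", "spring2014", "summer2015"),
    start = as.Date(c("2014-02-10", "2014-06-20", "2014-09-25", "2015-02-10")),
    n_secondary = 4L, secondary_len = 5L, stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  winter_off <- sample(station_ids, n - n_winter)
  study_design(station_ids, seasons,
               inactive = list(winter2014 = winter_off))
}

#' Simulate a complete synthetic study on disk
#'
#' Generates the landscape, design, latent dynamics, detection events and
#' sun-times table, writing them in the delimited-text / YAML formats the
#' readers consume, together with the serialized ground truth.
#'
#' @param dir Output directory (created if needed).
#' @param truth A [synthetic_truth()].
#' @param n_stations Number of stations.
#' @param seed Integer seed governing every draw.
#' @param header Optional comment string stamped on each delimited file.
#' @return Invisibly, a list of the in-memory objects and file paths.
#' @export
simulate_study <- function(dir, truth = synthetic_truth(), n_stations = 93,
                           seed = truth$seed, header = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stations <- simulate_landscape(n_stations, seed = derive_seed(seed, 1))
  design <- default_design(stations$id, seed = derive_seed(seed, 2))
  sim <- simulate_dynamics(truth, stations, design, seed = derive_seed(seed, 3))
  all_days <- as.Date(unlist(lapply(seq_len(nrow(design$seasons)), function(t)
    as.list(design$seasons$start[t] + seq_len(design$seasons$n_secondary[t] *
                                                design$seasons$secondary_len[t]) - 1))),
    origin = "1970-01-01")
  sun <- simulate_sun_times(all_days)

  paths <- list(stations = file.path(dir, "stations.csv"),
                detections = file.path(dir, "detections.csv"),
                design = file.path(dir, "design.yaml"),
                sun_times = file.path(dir, "sun_times.csv"),
                truth = file.path(dir, "truth.yaml"))
  write_csv_header <- function(df, path) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.csv(df, con, row.names = FALSE)
  }
  write_csv_header(stations, paths$stations)
  ev <- sim$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M")
  write_csv_header(ev, paths$detections)
  write_design(design, paths$design)
  write_csv_header(sun, paths$sun_times)
  write_truth(truth, paths$truth)
  invisible(list(stations = stations, design = design, sim = sim, sun = sun,
                 paths = paths))
}

#' Serialize / read synthetic ground truth
#'
#' @param truth A `synthetic_truth`.
#' @param path YAML path.
#' @export
write_truth <- function(truth, path) {
  obj <- list(psi1 = as.list(truth$psi1), gamma = as.list(truth$gamma),
              epsilon = as.list(truth$epsilon), p = as.list(truth$p),
              auto = as.list(truth$auto),
              neighbor_radius = truth$neighbor_radius,
              diel = truth$diel, event_geom_prob = truth$event_geom_prob,
              seed = truth$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  synthetic_truth(psi1 = unlist(obj$psi1), gamma = unlist(obj$gamma),
                  epsilon = unlist(obj$epsilon), p = unlist(obj$p),
                  auto = unlist(obj$auto),
                  neighbor_radius = obj$neighbor_radius,
                  diel = obj$diel, event_geom_prob = obj$event_geom_prob,
                  seed = obj$seed)
}
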