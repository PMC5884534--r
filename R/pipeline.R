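#' Read and validate a pipeline run configuration
#'
#' A single YAML file governs the whole analysis: the seed, the output
#' directory, input paths, the synthetic-truth block used by
#' [run_simulate()], and the fitting settings (independence gap, collinearity
#' threshold, neighbour radius, seasons entering the dynamic model, MCMC
#' sizes, stage candidates, inland-subset rule). No hidden defaults affect
#' inference without appearing in the resolved config echoed to the output
#' directory.
#'
#' @param path YAML config path.
#' @return A `run_config` list; `$hash` carries the file's md5.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  cfg <- yaml::read_yaml(path)
  cfg$hash <- unname(tools::md5sum(path))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$output_dir <- cfg$output_dir %||% "dynocc_out"
  cfg$paths <- cfg$paths %||% list()
  for (nm in c("stations", "detections", "design", "sun_times"))
    cfg$paths[[nm]] <- cfg$paths[[nm]] %||%
      file.path(cfg$output_dir, "data", paste0(nm, switch(nm,
        design = ".yaml", ".csv")))
  fit <- cfg$fit %||% list()
  fit$min_gap_minutes <- fit$min_gap_minutes %||% 60
  fit$collinearity_threshold <- fit$collinearity_threshold %||% 0.7
  fit$neighbor_radius <- fit$neighbor_radius %||% 1500
  fit$winter_season <- fit$winter_season %||% "winter2014"
  fit$mcmc <- fit$mcmc %||% list()
  cfg$fit <- fit
  class(cfg) <- "run_config"
  cfg
}

cfg_header <- function(cfg) sprintf("config=%s seed=%d", cfg$hash, cfg$seed)

log_stage <- function(cfg, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  logf <- file.path(cfg$output_dir, "run.log")
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  cat(msg, "\n", file = logf, append = TRUE)
  invisible(msg)
}

mcmc_from_config <- function(cfg) {
  m <- cfg$fit$mcmc
  mcmc_control(n_chains = m$n_chains %||% 3,
               n_iter = m$n_iter %||% 2000,
               n_burn = m$n_burn %||% 500,
               prior_sd = m$prior_sd %||% 31.6,
               z_draws = m$z_draws %||% 1000,
               paper_scale = isTRUE(m$paper_scale),
               seed = cfg$seed)
}

write_output_csv <- function(df, path, cfg) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", cfg_header(cfg)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Generate a synthetic study from a config
#'
#' Requires a `simulate` block with a `truth` entry (use `truth: default` for
#' the stock generating values, or a mapping overriding [synthetic_truth()]
#' arguments). Writes stations, detections, design, sun times and the
#' serialized truth under the configured paths, stamping the config hash and
#' seed on every delimited file.
#'
#' @param config A `run_config` or path to one.
#' @return Invisibly, the file paths.
#' @export
run_simulate <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  sim_cfg <- cfg$simulate
  if (is.null(sim_cfg) || is.null(sim_cfg$truth))
    stopf("config lacks a simulate$truth block")
  truth <- if (identical(sim_cfg$truth, "default")) synthetic_truth(seed = cfg$seed)
  else {
    tr <- sim_cfg$truth
    do.call(synthetic_truth, c(
      lapply(tr[intersect(names(tr), c("psi1", "gamma", "epsilon", "p",
                                       "auto"))], unlist),
      tr[intersect(names(tr), c("neighbor_radius", "diel",
                                "event_geom_prob"))],
      list(seed = cfg$seed)))
  }
  data_dir <- dirname(cfg$paths$stations)
  log_stage(cfg, "simulate: %d stations, seed %d",
            sim_cfg$n_stations %||% 93, cfg$seed)
  out <- simulate_study(data_dir, truth = truth,
                        n_stations = sim_cfg$n_stations %||% 93,
                        seed = cfg$seed, header = cfg_header(cfg))
  for (nm in c("stations", "detections", "sun_times"))
    if (!identical(out$paths[[nm]], cfg$paths[[nm]]))
      file.copy(out$paths[[nm]], cfg$paths[[nm]], overwrite = TRUE)
  if (!identical(out$paths$design, cfg$paths$design))
    file.copy(out$paths$design, cfg$paths$design, overwrite = TRUE)
  log_stage(cfg, "simulate: wrote %s", paste(unlist(out$paths), collapse = ", "))
  invisible(out$paths)
}

#' Run the full occupancy and activity analysis from a config
#'
#' History construction, collinearity screen, staged DIC selection of the
#' dynamic model (winter excluded), per-season single-season fits on the
#' inland subset (stations off the coast and closer to fresh water than to
#' the marine coast), PAO and response curves, the 50-m detection-rate table
#' and the per-season diel activity analysis. All outputs are delimited text
#' under the output directory, each stamped with the config hash and seed.
#'
#' @param config A `run_config` or path to one.
#' @return Invisibly, a list of output paths.
#' @export
run_fit <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  for (nm in c("stations", "detections", "design", "sun_times"))
    if (!file.exists(cfg$paths[[nm]]))
      stopf("input stage failed: missing %s file '%s'", nm, cfg$paths[[nm]])
  outdir <- cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  log_stage(cfg, "fit: reading inputs")
  stations <- read_stations(cfg$paths$stations)
  design <- read_design(cfg$paths$design)
  events_raw <- read_detections(cfg$paths$detections, stations)
  sun_table <- utils::read.csv(cfg$paths$sun_times, comment.char = "#",
                               stringsAsFactors = FALSE)

  log_stage(cfg, "fit: history construction (%d raw events)", nrow(events_raw))
  events <- filter_independent(events_raw, cfg$fit$min_gap_minutes)
  history <- build_history(events, design, stations)
  paths$history <- write_history(history, file.path(outdir, "history.csv"),
                                 header = cfg_header(cfg))

  log_stage(cfg, "fit: collinearity screen")
  covs <- c("elevation", "slope", "dist_coast", "dist_any_water",
            "dist_freshwater", "ground_cover")
  flagged <- collinearity_screen(stations, covs,
                                 cfg$fit$collinearity_threshold)
  paths$collinearity <- write_output_csv(flagged,
                                         file.path(outdir, "collinearity.csv"),
                                         cfg)
  if (nrow(flagged))
    log_stage(cfg, "fit: flagged pairs: %s",
              paste(flagged$cov1, flagged$cov2, sep = "~", collapse = ", "))

  # dynamic model: winter excluded
  dyn_seasons <- cfg$fit$dynamic_seasons %||%
    setdiff(design$seasons$label, cfg$fit$winter_season)
  dyn_hist <- subset_history(history, seasons = dyn_seasons)
  graph <- build_neighbor_graph(stations, cfg$fit$neighbor_radius)
  control <- mcmc_from_config(cfg)

  log_stage(cfg, "fit: staged forward selection over %d seasons",
            length(dyn_seasons))
  stages <- if (!is.null(cfg$fit$stages))
    do.call(selection_stages, lapply(cfg$fit$stages, function(s)
      lapply(s, as.character)))
  else selection_stages(
    detection = list("ground_cover", "dist_any_water"),
    initial_occupancy = list("elevation"),
    colonization = list("dist_any_water"),
    extinction = list("dist_any_water"))
  sel <- forward_select(stages, dyn_hist, stations, graph = graph,
                        control = control, flagged = flagged)
  paths$selection <- write_selection_table(sel,
                                           file.path(outdir, "selection_table.csv"),
                                           header = cfg_header(cfg))
  best_fit <- fit_occu(sel$spec, dyn_hist, stations, graph = graph,
                       control = control, flagged = flagged)
  if (!best_fit$converged)
    log_stage(cfg, "fit: WARNING final dynamic fit flagged non-converged (max R-hat %.3f)",
              max(best_fit$rhat))
  sm <- summary(best_fit)
  paths$dynamic_coefs <- write_output_csv(
    cbind(parameter = rownames(sm$coefficients), sm$coefficients),
    file.path(outdir, "dynamic_coefficients.csv"), cfg)

  log_stage(cfg, "fit: derived quantities (PAO, response curves)")
  coast_ids <- stations$id[stations$habitat == "coast_shrubland"]
  inland_ids <- setdiff(stations$id, coast_ids)
  pao_tab <- rbind(cbind(group = "all", pao(best_fit)),
                   cbind(group = "coast", pao(best_fit, sites = coast_ids)),
                   cbind(group = "inland", pao(best_fit, sites = inland_ids)))
  paths$pao <- write_output_csv(pao_tab, file.path(outdir, "pao.csv"), cfg)

  curves <- list()
  for (par in c("psi1", "gamma", "epsilon", "p")) {
    for (cov in setdiff(gsub("^I\\(|\\^2\\)$", "",
                             spec_terms(best_fit$spec, par)), "habitat")) {
      cv <- response_curve(best_fit, par, cov)
      curves[[length(curves) + 1]] <- cbind(parameter = par,
                                            name = cov, cv)
    }
  }
  if (length(curves))
    paths$response_curves <- write_output_csv(do.call(rbind, curves),
                                              file.path(outdir, "response_curves.csv"),
                                              cfg)

  # inland single-season fits: off-coast stations closer to fresh water
  inland <- stations[stations$habitat != "coast_shrubland" &
                       stations$dist_freshwater < stations$dist_coast, ,
                     drop = FALSE]
  log_stage(cfg, "fit: single-season inland fits (%d stations)", nrow(inland))
  p_terms <- sel$structure$p
  ss_rows <- list()
  for (season in design$seasons$label) {
    ids <- intersect(inland$id, design$station_ids[design$active[, season]])
    hist1 <- subset_history(history, seasons = season, sites = ids)
    sspec <- occu_spec(psi1 = ~dist_freshwater, p = term_formula(p_terms))
    sfit <- fit_single_season(sspec, hist1, inland, control = control)
    ssm <- summary(sfit)$coefficients
    ss_rows[[season]] <- cbind(season = season,
                               parameter = rownames(ssm), ssm)
  }
  paths$single_season <- write_output_csv(do.call(rbind, ss_rows),
                                          file.path(outdir, "single_season_coefficients.csv"),
                                          cfg)

  log_stage(cfg, "fit: detection rates by distance and capture rates")
  eff <- season_effort(design)
  inland_eff <- rowSums(eff)[inland$id]
  inland_events <- events[events$station_id %in% inland$id, , drop = FALSE]
  ddr <- detection_rate_by_distance(inland_events, inland, inland_eff,
                                    bin_width = cfg$fit$bin_width %||% 50)
  if (any(ddr$trap_nights == 0))
    log_stage(cfg, "fit: %d distance bin(s) with zero effort (rate undefined)",
              sum(ddr$trap_nights == 0))
  paths$detection_rate <- write_output_csv(ddr,
                                           file.path(outdir, "detection_rate.csv"),
                                           cfg)
  cr <- do.call(rbind, lapply(design$seasons$label, function(season) {
    t <- match(season, design$seasons$label)
    within <- vapply(seq_len(nrow(events)), function(r) {
      i <- match(events$station_id[r], design$station_ids)
      d0 <- deploy_start(design, i, t)
      day <- as.numeric(as.Date(format(events$timestamp[r], "%Y-%m-%d")) - d0)
      day >= 0 && day < design$seasons$n_secondary[t] *
        design$seasons$secondary_len[t]
    }, logical(1))
    data.frame(season = season, n_events = sum(within),
               trap_nights = sum(eff[, t]),
               rate = capture_rate(sum(within), sum(eff[, t])))
  }))
  paths$capture_rate <- write_output_csv(cr,
                                         file.path(outdir, "capture_rate.csv"),
                                         cfg)

  log_stage(cfg, "fit: diel activity per season")
  act_rows <- list()
  kde_rows <- list()
  for (season in design$seasons$label) {
    t <- match(season, design$seasons$label)
    days <- design$seasons$start[t] +
      seq_len(design$seasons$n_secondary[t] * design$seasons$secondary_len[t]) - 1
    hrs <- local({
      d <- as.Date(format(events$timestamp, "%Y-%m-%d"))
      sel_ev <- d %in% days
      tt <- events$timestamp[sel_ev]
      as.numeric(format(tt, "%H")) + as.numeric(format(tt, "%M")) / 60
    })
    if (length(hrs) < 2 || length(unique(hrs)) < 2) {
      log_stage(cfg, "fit: season %s has <2 detections, activity skipped",
                season)
      next
    }
    act <- activity_analysis(hrs, sun_table, dates = days,
                             use = cfg$fit$activity_use %||% "kde",
                             kappa = cfg$fit$kappa %||% "auto")
    act_rows[[season]] <- cbind(season = season, act$ratios,
                                n = length(hrs))
    kde_rows[[season]] <- data.frame(season = season, time = act$kde$grid,
                                     density = act$kde$density)
  }
  if (length(act_rows)) {
    paths$activity <- write_output_csv(do.call(rbind, act_rows),
                                       file.path(outdir, "activity_selection.csv"),
                                       cfg)
    paths$kde <- write_output_csv(do.call(rbind, kde_rows),
                                  file.path(outdir, "activity_kde.csv"), cfg)
  }

  cfg_echo <- cfg
  cfg_echo$hash <- NULL
  yaml::write_yaml(unclass(cfg_echo), file.path(outdir, "config_echo.yaml"))
  log_stage(cfg, "fit: done")
  invisible(paths)
}

#' Assemble a human-readable report from fit outputs
#'
#' Collects the PAO table, selection table, response curves, detection-rate
#' table and activity results into one markdown document with figures
#' rendered alongside. Errors list every missing stage output. Regeneration
#' is idempotent.
#'
#' @param config A `run_config` or path to one.
#' @return Invisibly, the report path.
#' @export
run_report <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else config
  outdir <- cfg$output_dir
  expected <- c(pao = "pao.csv", selection = "selection_table.csv",
                dynamic = "dynamic_coefficients.csv",
                single_season = "single_season_coefficients.csv",
                detection_rate = "detection_rate.csv",
                capture_rate = "capture_rate.csv",
                activity = "activity_selection.csv",
                kde = "activity_kde.csv")
  missing <- expected[!file.exists(file.path(outdir, expected))]
  if (length(missing))
    stopf("missing fit outputs for stage(s): %s",
          paste(names(missing), collapse = ", "))
  rd <- function(f) utils::read.csv(file.path(outdir, f), comment.char = "#",
                                    stringsAsFactors = FALSE)
  md <- c(sprintf("# Occupancy and diel activity report"),
          sprintf("_%s_", cfg_header(cfg)), "")
  tab_md <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 3))
    c(paste0("| ", paste(names(df), collapse = " | "), " |"),
      paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
      vapply(seq_len(nrow(df)), function(i)
        paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |"),
        character(1)), "")
  }
  md <- c(md, "## Proportion of area occupied", tab_md(rd("pao.csv")),
          "## Model selection", tab_md(rd("selection_table.csv")),
          "## Dynamic model coefficients", tab_md(rd("dynamic_coefficients.csv")),
          "## Single-season inland fits", tab_md(rd("single_season_coefficients.csv")),
          "## Capture rates", tab_md(rd("capture_rate.csv")),
          "## Detection rate by distance to fresh water",
          tab_md(rd("detection_rate.csv")),
          "## Diel activity selection ratios", tab_md(rd("activity_selection.csv")))

  fig_dir <- file.path(outdir, "figures")
  dir.create(fig_dir, recursive = TRUE, showWarnings = FALSE)
  kde <- rd("activity_kde.csv")
  for (season in unique(kde$season)) {
    f <- file.path(fig_dir, paste0("activity_", season, ".png"))
    grDevices::png(f, width = 700, height = 400)
    sub <- kde[kde$season == season, ]
    graphics::plot(sub$time, sub$density, type = "l",
                   xlab = "Hour of day", ylab = "Density", main = season)
    grDevices::dev.off()
    md <- c(md, sprintf("![activity %s](figures/activity_%s.png)", season,
                        season))
  }
  rc_path <- file.path(outdir, "response_curves.csv")
  if (file.exists(rc_path)) {
    rc <- rd("response_curves.csv")
    for (key in unique(paste(rc$parameter, rc$name))) {
      sub <- rc[paste(rc$parameter, rc$name) == key, ]
      f <- file.path(fig_dir, paste0("curve_", gsub(" ", "_", key), ".png"))
      grDevices::png(f, width = 700, height = 400)
      graphics::plot(sub$covariate, sub$mean, type = "l", ylim = c(0, 1),
                     xlab = sub$name[1], ylab = sub$parameter[1], main = key)
      graphics::lines(sub$covariate, sub$lower, lty = 2)
      graphics::lines(sub$covariate, sub$upper, lty = 2)
      grDevices::dev.off()
    }
  }
  report_path <- file.path(outdir, "report.md")
  writeLines(md, report_path)
  log_stage(cfg, "report: wrote %s", report_path)
  invisible(report_path)
}
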