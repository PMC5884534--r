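#' Build a detection history from independent events
#'
#' Collapses timestamped events into the site x season x secondary-period
#' binary array the occupancy models consume. An entry is 1 if at least one
#' event for that station falls inside the half-open secondary period, 0 if
#' the station was operative but recorded no event, and missing (NA) where the
#' station was not operative.
#'
#' @param events Independence-filtered events (`station_id`, `timestamp`).
#' @param design A [study_design()].
#' @param stations Station table (defines the site order via `design`).
#' @return A `detection_history`: list with `y` (array site x season x
#'   secondary, dimnames set), `effort` (trap-night matrix site x season) and
#'   the `design`.
#' @export
build_history <- function(events, design, stations) {
  ids <- design$station_ids
  if (!all(events$station_id %in% ids))
    stopf("event at station '%s' not present in design",
          setdiff(events$station_id, ids)[1])
  n <- length(ids)
  Tn <- nrow(design$seasons)
  K <- max(design$seasons$n_secondary)
  y <- array(NA_real_, c(n, Tn, K),
             dimnames = list(ids, design$seasons$label, paste0("k", seq_len(K))))
  for (t in seq_len(Tn)) {
    Kt <- design$seasons$n_secondary[t]
    y[design$active[, t], t, seq_len(Kt)] <- 0
  }
  if (nrow(events)) {
    ev_date <- as.Date(format(events$timestamp, "%Y-%m-%d"))
    for (r in seq_len(nrow(events))) {
      i <- match(events$station_id[r], ids)
      placed <- FALSE
      for (t in seq_len(Tn)) {
        start <- deploy_start(design, i, t)
        len <- design$seasons$secondary_len[t]
        Kt <- design$seasons$n_secondary[t]
        day <- as.numeric(ev_date[r] - start)
        if (day >= 0 && day < Kt * len) {
          if (!design$active[i, t])
            stopf("event at inactive station '%s' during season '%s'",
                  ids[i], design$seasons$label[t])
          y[i, t, floor(day / len) + 1] <- 1
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stopf("event at station '%s' on %s falls outside every season window",
              ids[i], format(ev_date[r]))
    }
  }
  structure(list(y = y, effort = season_effort(design), design = design),
            class = "detection_history")
}

#' @export
print.detection_history <- function(x, ...) {
  d <- dim(x$y)
  ndet <- sum(x$y == 1, na.rm = TRUE)
  cat(sprintf("Detection history: %d sites x %d seasons x %d secondary periods\n",
              d[1], d[2], d[3]))
  cat(sprintf("  %d site-period detections; %d site-seasons missing; %d total trap nights\n",
              ndet, sum(is.na(x$y[, , 1])), sum(x$effort)))
  invisible(x)
}

# Subset a history to chosen seasons and/or sites (labels or indices).
#' Subset a detection history
#'
#' @param history A `detection_history`.
#' @param seasons Season labels or indices to keep (default all).
#' @param sites Site ids or indices to keep (default all).
#' @return The subsetted `detection_history`.
#' @export
subset_history <- function(history, seasons = NULL, sites = NULL) {
  des <- history$design
  ti <- if (is.null(seasons)) seq_len(nrow(des$seasons))
        else if (is.character(seasons)) match(seasons, des$seasons$label)
        else seasons
  si <- if (is.null(sites)) seq_along(des$station_ids)
        else if (is.character(sites)) match(sites, des$station_ids)
        else sites
  if (anyNA(ti)) stopf("unknown season label")
  if (anyNA(si)) stopf("unknown site id")
  des2 <- des
  des2$seasons <- des$seasons[ti, , drop = FALSE]
  des2$active <- des$active[si, ti, drop = FALSE]
  des2$station_ids <- des$station_ids[si]
  des2$start_offset <- des$start_offset[si]
  structure(list(y = history$y[si, ti, , drop = FALSE],
                 effort = history$effort[si, ti, drop = FALSE],
                 design = des2),
            class = "detection_history")
}

#' Write a detection history as delimited text
#'
#' One row per site-season with columns `site, season, k1..kK` (NA for
#' missing) plus the effort column.
#'
#' @param history A `detection_history`.
#' @param path Output path.
#' @param header Optional comment line (without `#`) written on top.
#' @export
write_history <- function(history, path, header = NULL) {
  d <- dim(history$y)
  rows <- do.call(rbind, lapply(seq_len(d[2]), function(t) {
    df <- as.data.frame(history$y[, t, , drop = TRUE])
    names(df) <- paste0("k", seq_len(d[3]))
    cbind(data.frame(site = dimnames(history$y)[[1]],
                     season = dimnames(history$y)[[2]][t],
                     stringsAsFactors = FALSE),
          df, effort = history$effort[, t])
  }))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(rows, con, row.names = FALSE, na = "NA")
  invisible(path)
}
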