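#' Read timestamped detection events
#'
#' @param path Comma-delimited file with header columns `station_id` and
#'   `timestamp` (ISO 8601, minute resolution, e.g. `2014-02-12T04:30`).
#'   Lines starting with `#` are ignored.
#' @param stations Optional station table; events at unknown stations are
#'   rejected when supplied.
#' @return A data frame of events with columns `station_id` (character) and
#'   `timestamp` (`POSIXct`, UTC), in file order.
#' @export
read_detections <- function(path, stations = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  if (!all(c("station_id", "timestamp") %in% names(df)))
    stopf("detections file needs columns station_id, timestamp")
  ts <- parse_iso_datetime(df$timestamp)
  bad <- which(is.na(ts))
  if (length(bad))
    stopf("malformed timestamp '%s' in row %d", df$timestamp[bad[1]], bad[1])
  if (!is.null(stations)) {
    unknown <- which(!df$station_id %in% stations$id)
    if (length(unknown))
      stopf("unknown station id '%s' in row %d",
            df$station_id[unknown[1]], unknown[1])
  }
  data.frame(station_id = df$station_id, timestamp = ts,
             stringsAsFactors = FALSE)
}

# Strict ISO 8601 parser (date or date+time); rejects impossible dates that
# strptime would silently roll over.
parse_iso_datetime <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"),
                   optional = TRUE)
  # round-trip check catches e.g. month 13 rolling into the next year
  ok <- !is.na(ts) & substr(format(ts, "%Y-%m-%d"), 1, 10) == substr(x, 1, 10)
  ts[!ok] <- NA
  ts
}

#' Thin detections to independent events
#'
#' Applies the standard independence rule for camera-trap data: within each
#' station, an event is kept iff it is the first or falls strictly more than
#' `min_gap_minutes` after the last *kept* event (greedy forward pass).
#' Stations never interact. The rule is idempotent.
#'
#' @param events Event data frame (`station_id`, `timestamp`).
#' @param min_gap_minutes Minimum separation in minutes (default 60); an event
#'   exactly at the gap is discarded.
#' @return The filtered events, sorted by station then time.
#' @export
filter_independent <- function(events, min_gap_minutes = 60) {
  if (min_gap_minutes <= 0) stopf("min_gap_minutes must be > 0")
  if (nrow(events) == 0) return(events)
  events <- events[order(events$station_id, events$timestamp), , drop = FALSE]
  keep <- logical(nrow(events))
  for (st in unique(events$station_id)) {
    idx <- which(events$station_id == st)
    last_kept <- -Inf
    for (i in idx) {
      ti <- as.numeric(events$timestamp[i])
      if (ti - last_kept > min_gap_minutes * 60) {
        keep[i] <- TRUE
        last_kept <- ti
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Capture rate per 100 trap nights
#'
#' @param events Event data frame (already independence-filtered), or an
#'   integer count of events.
#' @param effort_trap_nights Total trap nights (> 0).
#' @return Detections per 100 trap nights.
#' @export
capture_rate <- function(events, effort_trap_nights) {
  if (effort_trap_nights <= 0) stopf("effort must be > 0")
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  100 * n / effort_trap_nights
}

#' Detection rate binned by distance to fresh water
#'
#' Bins stations into half-open distance segments `[b, b + width)` by their
#' distance to fresh water and reports the detection rate per 100 trap nights
#' in each segment. Segments with zero effort have an undefined (NA) rate,
#' never zero.
#'
#' @param events Independence-filtered events.
#' @param stations Station table carrying `dist_freshwater`.
#' @param effort Named vector of trap nights per station id.
#' @param bin_width Segment width in metres (default 50).
#' @return Data frame: `bin_start`, `bin_end`, `trap_nights`, `n_events`,
#'   `rate` (per 100 trap nights; NA where `trap_nights` is 0).
#' @export
detection_rate_by_distance <- function(events, stations, effort,
                                       bin_width = 50) {
  if (bin_width <= 0) stopf("bin_width must be > 0")
  d <- stats::setNames(stations$dist_freshwater, stations$id)
  eff <- stats::setNames(rep(0, nrow(stations)), stations$id)
  eff[names(effort)] <- effort
  max_d <- max(d, 0)
  breaks <- seq(0, (floor(max_d / bin_width) + 1) * bin_width, by = bin_width)
  bin_of <- function(x) pmin(findInterval(x, breaks), length(breaks) - 1)
  st_bin <- bin_of(d)
  nb <- length(breaks) - 1
  trap_nights <- vapply(seq_len(nb), function(b) sum(eff[st_bin == b]),
                        numeric(1))
  ev_bin <- if (nrow(events)) st_bin[match(events$station_id, stations$id)]
            else integer(0)
  n_events <- tabulate(ev_bin, nbins = nb)
  rate <- ifelse(trap_nights > 0, 100 * n_events / trap_nights, NA_real_)
  data.frame(bin_start = breaks[-length(breaks)], bin_end = breaks[-1],
             trap_nights = trap_nights, n_events = n_events, rate = rate)
}
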