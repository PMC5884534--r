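#' Define a camera-trap study design
#'
#' A design declares the survey seasons (primary periods), how each season is
#' split into secondary sampling periods, and which stations were operative in
#' each season. The default mirrors a common camera-trap protocol: each season
#' a camera runs continuously and its record is collapsed into four 5-day
#' secondary periods (20 trap nights per operative station per season).
#' Secondary periods are half-open day intervals aligned to each station's own
#' deployment start (the season start plus an optional per-station offset),
#' accommodating surveys run in sequential station groups.
#'
#' @param station_ids Character vector of station ids (defines row order).
#' @param seasons Data frame with columns `label`, `start` (coercible to
#'   `Date`), `n_secondary`, `secondary_len` (days).
#' @param inactive Optional named list: season label -> character vector of
#'   station ids not operative that season (contributing only missing
#'   observations).
#' @param start_offset Optional named numeric vector of per-station deployment
#'   start offsets in days (default 0 for all stations).
#' @return A `study_design` object.
#' @export
study_design <- function(station_ids, seasons, inactive = list(),
                         start_offset = NULL) {
  seasons <- as.data.frame(seasons, stringsAsFactors = FALSE)
  needed <- c("label", "start", "n_secondary", "secondary_len")
  if (!all(needed %in% names(seasons)))
    stopf("seasons needs columns: %s", paste(needed, collapse = ", "))
  seasons$start <- as.Date(seasons$start)
  if (anyDuplicated(seasons$label)) stopf("duplicated season labels")
  active <- matrix(TRUE, length(station_ids), nrow(seasons),
                   dimnames = list(station_ids, seasons$label))
  for (lab in names(inactive)) {
    if (!lab %in% seasons$label) stopf("inactive refers to unknown season '%s'", lab)
    ids <- inactive[[lab]]
    unknown <- setdiff(ids, station_ids)
    if (length(unknown))
      stopf("inactive station id(s) not in design: %s",
            paste(unknown, collapse = ", "))
    active[ids, lab] <- FALSE
  }
  off <- stats::setNames(rep(0, length(station_ids)), station_ids)
  if (!is.null(start_offset)) off[names(start_offset)] <- start_offset
  structure(list(station_ids = station_ids, seasons = seasons,
                 active = active, start_offset = off),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d stations, %d seasons\n",
              length(x$station_ids), nrow(x$seasons)))
  for (t in seq_len(nrow(x$seasons)))
    cat(sprintf("  %-12s start %s, %d x %d-day secondary periods, %d stations operative\n",
                x$seasons$label[t], format(x$seasons$start[t]),
                x$seasons$n_secondary[t], x$seasons$secondary_len[t],
                sum(x$active[, t])))
  invisible(x)
}

#' Trap-night effort per station and season
#'
#' @param design A `study_design`.
#' @return Matrix (station x season) of trap nights: `n_secondary *
#'   secondary_len` where operative, 0 elsewhere.
#' @export
season_effort <- function(design) {
  nights <- design$seasons$n_secondary * design$seasons$secondary_len
  eff <- sweep(design$active * 1, 2, nights, `*`)
  dimnames(eff) <- dimnames(design$active)
  eff
}

# Deployment window start (Date) for station i in season t.
deploy_start <- function(design, i, t) {
  design$seasons$start[t] + design$start_offset[[design$station_ids[i]]]
}

#' Read a study design from a YAML config
#'
#' @param path YAML file with keys `seasons` (list of label/start/n_secondary/
#'   secondary_len), optional `inactive` (season -> id list), optional
#'   `start_offset` (id -> days), and `station_ids`.
#' @return A `study_design`.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  seasons <- do.call(rbind, lapply(cfg$seasons, function(s)
    data.frame(label = s$label, start = s$start,
               n_secondary = s$n_secondary, secondary_len = s$secondary_len,
               stringsAsFactors = FALSE)))
  study_design(cfg$station_ids, seasons,
               inactive = cfg$inactive %||% list(),
               start_offset = unlist(cfg$start_offset))
}

#' Write a study design to YAML
#'
#' @param design A `study_design`.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  cfg <- list(
    station_ids = as.list(design$station_ids),
    seasons = lapply(seq_len(nrow(design$seasons)), function(t)
      list(label = design$seasons$label[t],
           start = format(design$seasons$start[t]),
           n_secondary = design$seasons$n_secondary[t],
           secondary_len = design$seasons$secondary_len[t])),
    inactive = {
      ia <- lapply(design$seasons$label, function(lab)
        as.list(design$station_ids[!design$active[, lab]]))
      names(ia) <- design$seasons$label
      ia[vapply(ia, length, integer(1)) > 0]
    },
    start_offset = as.list(design$start_offset[design$start_offset != 0])
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}
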