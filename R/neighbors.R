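#' Build a neighbour graph from station coordinates
#'
#' Neighbours are all other stations within a planar Euclidean radius.
#' Coordinates are assumed projected, in metres. The default radius of
#' 1500 m sits between typical inland (~810 m) and coastal (~2000 m) station
#' spacings; it is an analysis choice, not an estimated quantity.
#'
#' @param stations Station table with `x`, `y`.
#' @param radius_m Neighbour radius in metres (> 0).
#' @return A `neighbor_graph`: list with `neighbors` (list of integer indices
#'   per site), `n` (neighbour counts) and `ids`.
#' @export
build_neighbor_graph <- function(stations, radius_m = 1500) {
  if (radius_m <= 0) stopf("radius_m must be > 0")
  xy <- as.matrix(stations[, c("x", "y")])
  dm <- as.matrix(stats::dist(xy))
  nb <- lapply(seq_len(nrow(xy)), function(i) {
    j <- unname(which(dm[i, ] <= radius_m))
    j[j != i]
  })
  structure(list(neighbors = nb,
                 n = vapply(nb, length, integer(1)),
                 ids = stations$id, radius_m = radius_m),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("Neighbour graph: %d sites, radius %g m, mean %.1f neighbours, %d isolated\n",
              length(x$n), x$radius_m, mean(x$n), sum(x$n == 0)))
  invisible(x)
}

#' Spatiotemporal auto-covariate
#'
#' For each site, the mean latent occupancy state of its neighbours:
#' `D_i = (1/n_i) sum_{j in N_i} z_j`. Isolated sites (no neighbours) get
#' `D_i = 0` with a warning.
#'
#' @param z_season Binary vector of latent states for one season.
#' @param graph A [build_neighbor_graph()] result.
#' @return Numeric vector `D` in `[0, 1]`.
#' @export
auto_covariate <- function(z_season, graph) {
  if (length(z_season) != length(graph$n))
    stopf("z and graph dimensions disagree")
  if (any(graph$n == 0))
    warnf("%d isolated site(s): auto-covariate set to 0", sum(graph$n == 0))
  vapply(seq_along(z_season), function(i) {
    if (graph$n[i] == 0) 0 else mean(z_season[graph$neighbors[[i]]])
  }, numeric(1))
}
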