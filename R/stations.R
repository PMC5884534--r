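#' Read a station covariate table
#'
#' Reads the per-station table of coordinates, habitat class and habitat
#' covariates used by every linear predictor in the occupancy models.
#'
#' @param path Path to a comma-delimited file with header columns
#'   `id, x, y, habitat, elevation, slope, dist_coast, dist_any_water,
#'   dist_freshwater, ground_cover`. Lines starting with `#` are ignored.
#' @return A `data.frame` with one row per station; `habitat` is a factor
#'   with levels `coast_shrubland`, `forest`, `meadow`.
#' @export
read_stations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_stations(df)
}

#' Validate a station table
#'
#' Checks column presence, habitat classes, distance positivity and the
#' ground-cover range, returning the table with `habitat` as a factor.
#'
#' @param stations A data frame of stations (see [read_stations()]).
#' @return The validated station table.
#' @export
validate_stations <- function(stations) {
  needed <- c("id", "x", "y", "habitat", "elevation", "slope", "dist_coast",
              "dist_any_water", "dist_freshwater", "ground_cover")
  missing <- setdiff(needed, names(stations))
  if (length(missing))
    stopf("station table lacks columns: %s", paste(missing, collapse = ", "))
  if (anyDuplicated(stations$id))
    stopf("duplicated station ids")
  bad <- setdiff(unique(as.character(stations$habitat)), HABITATS)
  if (length(bad))
    stopf("unknown habitat class(es): %s", paste(bad, collapse = ", "))
  dist_cols <- c("dist_coast", "dist_any_water", "dist_freshwater")
  for (cl in dist_cols)
    if (any(stations[[cl]] < 0)) stopf("negative values in %s", cl)
  if (any(stations$ground_cover < 0 | stations$ground_cover > 100))
    stopf("ground_cover outside [0, 100]")
  stations$habitat <- factor(as.character(stations$habitat), levels = HABITATS)
  stations
}

#' Standardize station covariates
#'
#' Centers and scales the named covariates to mean 0 and sample (n - 1)
#' standard deviation 1, recording the scaling so model response curves can be
#' mapped back to raw covariate units.
#'
#' @param stations Station table.
#' @param covariates Character vector of column names to standardize.
#' @return A list with elements `stations` (the table with the named columns
#'   replaced by their standardized values) and `scaling` (a
#'   `covariate_scaling` data frame of per-covariate `mean` and `sd`).
#' @export
standardize_covariates <- function(stations, covariates) {
  sc <- data.frame(covariate = covariates,
                   mean = NA_real_, sd = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_along(covariates)) {
    nm <- covariates[k]
    if (!nm %in% names(stations)) stopf("no covariate column '%s'", nm)
    x <- stations[[nm]]
    m <- mean(x)
    s <- stats::sd(x)  # sample sd, n - 1 denominator
    if (!is.finite(s) || s <= 0) stopf("covariate '%s' has zero variance", nm)
    stations[[nm]] <- (x - m) / s
    sc$mean[k] <- m
    sc$sd[k] <- s
  }
  class(sc) <- c("covariate_scaling", "data.frame")
  list(stations = stations, scaling = sc)
}

#' Invert covariate standardization
#'
#' @param values Standardized values.
#' @param scaling A `covariate_scaling` object from [standardize_covariates()].
#' @param covariate Covariate name.
#' @return Values on the raw scale.
#' @export
unstandardize <- function(values, scaling, covariate) {
  i <- match(covariate, scaling$covariate)
  if (is.na(i)) stopf("covariate '%s' not present in scaling", covariate)
  values * scaling$sd[i] + scaling$mean[i]
}

#' Screen covariate pairs for collinearity
#'
#' Computes Spearman rank correlations between all pairs of the named
#' covariates and flags pairs at or above the threshold. Model building
#' refuses specifications that combine a flagged pair unless overridden.
#'
#' @param stations Station table.
#' @param covariates Covariate column names to screen.
#' @param threshold Absolute Spearman correlation at or above which a pair is
#'   flagged; default 0.7.
#' @return A data frame with columns `cov1`, `cov2`, `rho` holding the flagged
#'   pairs (zero rows when none are flagged).
#' @export
collinearity_screen <- function(stations, covariates, threshold = 0.7) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  out <- data.frame(cov1 = character(0), cov2 = character(0),
                    rho = numeric(0), stringsAsFactors = FALSE)
  if (length(covariates) < 2) return(out)
  for (a in seq_len(length(covariates) - 1)) {
    for (b in seq(a + 1, length(covariates))) {
      rho <- stats::cor(stations[[covariates[a]]], stations[[covariates[b]]],
                        method = "spearman")
      if (is.finite(rho) && abs(rho) >= threshold)
        out <- rbind(out, data.frame(cov1 = covariates[a], cov2 = covariates[b],
                                     rho = rho, stringsAsFactors = FALSE))
    }
  }
  out
}

# TRUE when a term set uses both members of any flagged pair.
uses_flagged_pair <- function(term_names, flagged) {
  if (is.null(flagged) || nrow(flagged) == 0) return(FALSE)
  base <- unique(gsub("^I\\(|\\^2\\)$", "", term_names))
  any(vapply(seq_len(nrow(flagged)), function(i)
    flagged$cov1[i] %in% base && flagged$cov2[i] %in% base, logical(1)))
}
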