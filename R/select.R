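#' Declare staged model-selection candidates
#'
#' The staged forward procedure first structures detection, then initial
#' occupancy, then the dynamics (colonization, then extinction), freezing
#' each stage's winner before moving on. Each stage lists candidate term
#' units for one parameter: a unit is a character vector of model terms added
#' together (e.g. `c("dist_any_water", "I(dist_any_water^2)")` for a
#' quadratic), or `"auto"` for the neighbour auto-covariate (dynamics only).
#'
#' @param detection,initial_occupancy,colonization,extinction Lists of
#'   candidate term units for `p`, `psi1`, `gamma`, `epsilon`.
#' @return A list of stage definitions for [forward_select()].
#' @export
selection_stages <- function(
    detection = list("ground_cover", "dist_any_water"),
    initial_occupancy = list("elevation", "slope", "dist_any_water", "habitat"),
    colonization = list("dist_any_water",
                        c("dist_any_water", "I(dist_any_water^2)"),
                        "dist_coast", "auto"),
    extinction = list("dist_any_water",
                      c("dist_any_water", "I(dist_any_water^2)"),
                      "dist_coast", "auto")) {
  stages <- list(
    list(name = "detection", parameter = "p",
         candidates = lapply(detection, as.character)),
    list(name = "initial_occupancy", parameter = "psi1",
         candidates = lapply(initial_occupancy, as.character)),
    list(name = "colonization", parameter = "gamma",
         candidates = lapply(colonization, as.character)),
    list(name = "extinction", parameter = "epsilon",
         candidates = lapply(extinction, as.character)))
  stages[vapply(stages, function(s) length(s$candidates) > 0, logical(1))]
}

term_formula <- function(terms) {
  terms <- setdiff(terms, "auto")
  if (length(terms) == 0) ~1 else stats::reformulate(terms)
}

spec_from_structure <- function(structure_terms) {
  auto <- character(0)
  for (par in c("gamma", "epsilon"))
    if ("auto" %in% structure_terms[[par]]) auto <- c(auto, par)
  occu_spec(psi1 = term_formula(structure_terms$psi1),
            gamma = term_formula(structure_terms$gamma),
            epsilon = term_formula(structure_terms$epsilon),
            p = term_formula(structure_terms$p),
            auto = auto)
}

model_label <- function(structure_terms) {
  one <- function(par) {
    tt <- structure_terms[[par]]
    paste0(par, "(", if (length(tt)) paste(tt, collapse = "+") else ".", ")")
  }
  paste(vapply(c("psi1", "gamma", "epsilon", "p"), one, character(1)),
        collapse = " ")
}

#' Staged forward model selection by DIC
#'
#' At each stage the stage null (the structure frozen so far) and every
#' single-unit candidate are fitted; a candidate is informative iff its DIC
#' is below the null's. While at least one candidate is informative, the
#' procedure steps forward greedily, adding the best unit and retrying the
#' remaining ones while DIC keeps decreasing. Ties break toward the simpler
#' model. Candidates that fail to converge are excluded with a note, and
#' candidates combining collinearity-flagged covariates are skipped. The full
#' audit table — every fitted model, its DIC, pD and convergence flag — is
#' returned alongside the winner; DIC differences are suggestive, so the
#' table, not just the winner, is the product.
#'
#' @param stages Stage list from [selection_stages()].
#' @param history A `detection_history`.
#' @param stations Station table.
#' @param graph Neighbour graph (needed when any candidate is `"auto"`).
#' @param control An [mcmc_control()]; each fit derives its own seed from it.
#' @param flagged Collinearity table from [collinearity_screen()].
#' @return A `selection_result`: list with `spec` (winning [occu_spec()]),
#'   `structure` (term lists), `table` (audit data frame), `fits` (the stage
#'   winners' fits, named by stage).
#' @export
forward_select <- function(stages, history, stations, graph = NULL,
                           control = mcmc_control(), flagged = NULL) {
  structure_terms <- list(psi1 = character(0), gamma = character(0),
                          epsilon = character(0), p = character(0))
  rows <- list()
  winner_fits <- list()
  fit_counter <- 0L

  fit_structure <- function(st) {
    fit_counter <<- fit_counter + 1L
    sp <- spec_from_structure(st)
    ctl <- control
    ctl$seed <- derive_seed(control$seed, 1000L + fit_counter)
    fit_occu(sp, history, stations, graph = graph, control = ctl)
  }

  for (stage in stages) {
    par <- stage$parameter
    null_terms <- structure_terms
    null_fit <- fit_structure(null_terms)
    null_dic <- dic(null_fit)
    rows[[length(rows) + 1]] <- data.frame(
      stage = stage$name, model = model_label(null_terms),
      dic = null_dic$dic, delta_dic = 0, pd = null_dic$pd,
      mean_deviance = null_dic$mean_deviance,
      converged = null_fit$converged, note = "stage null",
      stringsAsFactors = FALSE)

    current_terms <- character(0)
    current_dic <- null_dic$dic
    current_fit <- null_fit
    remaining <- stage$candidates
    repeat {
      best <- NULL
      keep <- rep(TRUE, length(remaining))
      for (ci in seq_along(remaining)) {
        unit <- remaining[[ci]]
        trial <- structure_terms
        trial[[par]] <- union(current_terms, unit)
        if (identical(sort(trial[[par]]), sort(current_terms))) {
          keep[ci] <- FALSE
          next
        }
        if ("auto" %in% unit && !par %in% c("gamma", "epsilon")) {
          keep[ci] <- FALSE
          next
        }
        all_terms <- unlist(trial)
        if (uses_flagged_pair(all_terms, flagged)) {
          rows[[length(rows) + 1]] <- data.frame(
            stage = stage$name,
            model = model_label(trial), dic = NA_real_, delta_dic = NA_real_,
            pd = NA_real_, mean_deviance = NA_real_, converged = NA,
            note = "skipped: collinearity-flagged pair",
            stringsAsFactors = FALSE)
          keep[ci] <- FALSE
          next
        }
        fit <- fit_structure(trial)
        ic <- dic(fit)
        note <- if (!fit$converged) "excluded: non-convergence"
                else if (length(spec_from_structure(trial)$auto))
                  "conditional-deviance scale" else ""
        rows[[length(rows) + 1]] <- data.frame(
          stage = stage$name, model = model_label(trial), dic = ic$dic,
          delta_dic = ic$dic - null_dic$dic, pd = ic$pd,
          mean_deviance = ic$mean_deviance, converged = fit$converged,
          note = note, stringsAsFactors = FALSE)
        # strict inequality: ties break toward the simpler current model
        if (fit$converged && ic$dic < current_dic &&
            (is.null(best) || ic$dic < best$dic)) {
          best <- list(unit = unit, dic = ic$dic, fit = fit, ci = ci)
        }
      }
      remaining <- remaining[keep]
      if (is.null(best)) break
      current_terms <- union(current_terms, best$unit)
      current_dic <- best$dic
      current_fit <- best$fit
      drop_i <- Position(function(u) identical(u, best$unit), remaining)
      if (!is.null(drop_i) && !is.na(drop_i)) remaining <- remaining[-drop_i]
      if (!length(remaining)) break
    }
    structure_terms[[par]] <- current_terms
    winner_fits[[stage$name]] <- current_fit
  }

  table <- do.call(rbind, rows)
  structure(list(spec = spec_from_structure(structure_terms),
                 structure = structure_terms, table = table,
                 fits = winner_fits),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("Staged forward selection (DIC):\n")
  tab <- x$table
  tab$dic <- round(tab$dic, 1)
  tab$delta_dic <- round(tab$delta_dic, 1)
  tab$pd <- round(tab$pd, 1)
  tab$mean_deviance <- round(tab$mean_deviance, 1)
  print(tab, row.names = FALSE)
  cat("\nSelected structure:\n")
  print(x$spec)
  invisible(x)
}

#' Write a selection table as delimited text
#'
#' @param result A `selection_result`.
#' @param path Output path.
#' @param header Optional comment line.
#' @export
write_selection_table <- function(result, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.csv(result$table, con, row.names = FALSE)
  invisible(path)
}
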