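## Fitness landscape: lambda over the height x seed-weight trait grid,
## contour extraction, species projection and viability summaries.

#' Trait grid for the fitness sweep
#'
#' Defaults reproduce the published sweep: height 10-200 cm in 10 cm steps
#' and seed weight 0.01-20 mg in 0.01 mg steps (20 x 2000 cells).
#'
#' @param heights Strictly increasing heights, cm.
#' @param seed_weights Strictly increasing seed weights, mg.
#' @return A `trait_grid`.
#' @export
trait_grid <- function(heights = seq(10, 200, by = 10),
                       seed_weights = seq(0.01, 20, by = 0.01)) {
  if (any(diff(heights) <= 0) || any(diff(seed_weights) <= 0)) {
    wf_validation_error("grid axes must be strictly increasing")
  }
  if (any(heights <= 0) || any(seed_weights <= 0)) {
    wf_validation_error("grid axes must be strictly positive")
  }
  structure(list(heights = heights, seed_weights = seed_weights),
            class = "trait_grid")
}

#' Sweep lambda over a trait grid
#'
#' Runs [run_lifecycle()] at every grid cell (vectorised; the default
#' 40,000-cell grid takes well under a second).
#'
#' @param grid A `trait_grid`.
#' @param scenario A `scenario`.
#' @param params Calibrated `lifecycle_params`.
#' @param models Trait models list.
#' @return A `fitness_surface`: list with `grid`, `scenario` and `lambda`,
#'   a heights-by-seed-weights matrix.
#' @export
sweep_fitness <- function(grid, scenario, params, models = default_trait_models()) {
  nh <- length(grid$heights)
  ns <- length(grid$seed_weights)
  weed <- virtual_weed(rep(grid$heights, times = ns),
                       rep(grid$seed_weights, each = nh))
  res <- run_lifecycle(weed, scenario, params, models)
  lambda <- matrix(res$lambda, nrow = nh, ncol = ns,
                   dimnames = list(format(grid$heights, trim = TRUE),
                                   format(grid$seed_weights, trim = TRUE)))
  structure(list(grid = grid, scenario = scenario, lambda = lambda),
            class = "fitness_surface")
}

#' Export / re-import a fitness surface as delimited text
#'
#' Layout: first row is the seed-weight axis, first column the height axis,
#' body is lambda.
#'
#' @param surface A `fitness_surface`.
#' @param path Output CSV path.
#' @return `export_surface()` returns `path` invisibly; `read_surface()`
#'   returns a `fitness_surface` (scenario unknown, set to `NULL`).
#' @export
export_surface <- function(surface, path) {
  m <- surface$lambda
  out <- cbind(height = surface$grid$heights, as.data.frame(m, check.names = FALSE))
  names(out) <- c("height", format(surface$grid$seed_weights, trim = TRUE, digits = 15))
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE),
    error = function(e) wf_io_error(conditionMessage(e))
  )
  invisible(path)
}

#' @rdname export_surface
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) wf_io_error(sprintf("surface file '%s' does not exist", path))
  df <- utils::read.csv(path, check.names = FALSE)
  heights <- df[[1]]
  seed_weights <- as.numeric(names(df)[-1])
  lambda <- as.matrix(df[, -1, drop = FALSE])
  dimnames(lambda) <- list(format(heights, trim = TRUE),
                           format(seed_weights, trim = TRUE))
  structure(list(grid = trait_grid(heights, seed_weights), scenario = NULL,
                 lambda = lambda),
            class = "fitness_surface")
}

#' Extract fitness contours
#'
#' Level sets of lambda on the trait plane via marching squares
#' ([grDevices::contourLines()]); the default level 1 separates predicted
#' population growth from decline.
#'
#' @param surface A `fitness_surface`.
#' @param levels Lambda levels (default 1).
#' @return Data frame with columns `level`, `contour_id`, `height`,
#'   `seed_weight` (polyline vertex sequences); zero rows when no contour
#'   crosses the surface.
#' @export
extract_contours <- function(surface, levels = 1) {
  # contourLines warns on constant surfaces; an empty contour set is the
  # documented result there, not a user-facing problem
  cl <- suppressWarnings(grDevices::contourLines(x = surface$grid$heights,
                                                y = surface$grid$seed_weights,
                                                z = surface$lambda,
                                                levels = levels))
  if (!length(cl)) {
    return(data.frame(level = numeric(0), contour_id = integer(0),
                      height = numeric(0), seed_weight = numeric(0)))
  }
  do.call(rbind, lapply(seq_along(cl), function(k) {
    data.frame(level = cl[[k]]$level, contour_id = k,
               height = cl[[k]]$x, seed_weight = cl[[k]]$y)
  }))
}

#' @rdname extract_contours
#' @param path Output CSV path for the vertex table.
#' @export
export_contours <- function(surface, levels = 1, path) {
  ct <- extract_contours(surface, levels)
  tryCatch(
    utils::write.csv(ct, path, row.names = FALSE),
    error = function(e) wf_io_error(conditionMessage(e))
  )
  invisible(path)
}

#' Read / write a species list
#'
#' Delimited-text interface: columns `name`, `height_cm`, `seed_weight_mg`,
#' `status` (`common` or `rare_declining`).
#'
#' @param path CSV path.
#' @return A `species_records` data frame with columns `name`, `height`,
#'   `seed_weight`, `status`.
#' @export
read_species_list <- function(path) {
  if (!file.exists(path)) wf_io_error(sprintf("species list '%s' does not exist", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "height_cm", "seed_weight_mg", "status")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    wf_format_error(paste("species list lacks column(s):",
                          paste(missing_cols, collapse = ", ")))
  }
  out <- data.frame(name = df$name,
                    height = as.numeric(df$height_cm),
                    seed_weight = as.numeric(df$seed_weight_mg),
                    status = df$status, stringsAsFactors = FALSE)
  class(out) <- c("species_records", "data.frame")
  out
}

#' @rdname read_species_list
#' @param species A `species_records` data frame.
#' @export
write_species_list <- function(species, path) {
  out <- data.frame(name = species$name, height_cm = species$height,
                    seed_weight_mg = species$seed_weight,
                    status = species$status)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Project species onto the fitness landscape
#'
#' Lambda is computed from [run_lifecycle()] at each species' exact trait
#' values (no grid interpolation; the grid exists only for contours).
#' Traits outside the sweep domain are clamped and flagged.  Species with a
#' missing trait are skipped with a warning and counted in the
#' `"n_skipped"` attribute.
#'
#' @param species A `species_records` data frame.
#' @param scenarios Named list of `scenario` objects (default
#'   [standard_scenarios()]).
#' @param params Calibrated `lifecycle_params`.
#' @param models Trait models list.
#' @param threshold Viability threshold on lambda (default 1).
#' @param comparator `"ge"` (default, `lambda >= threshold`) or `"gt"`.
#' @return A `species_projection` data frame: traits, `clamped` flag and,
#'   per scenario `s`, columns `lambda_s` and `viable_s`.
#' @export
project_species <- function(species, scenarios = standard_scenarios(),
                            params, models = default_trait_models(),
                            threshold = 1, comparator = c("ge", "gt")) {
  comparator <- match.arg(comparator)
  ok <- is.finite(species$height) & is.finite(species$seed_weight) &
    !is.na(species$height) & !is.na(species$seed_weight)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(sprintf("skipping %d species with missing trait value(s): %s",
                    n_skipped, paste(species$name[!ok], collapse = ", ")),
            call. = FALSE)
    species <- species[ok, , drop = FALSE]
  }
  h <- pmin(pmax(species$height, HEIGHT_DOMAIN[1]), HEIGHT_DOMAIN[2])
  sw <- pmin(pmax(species$seed_weight, SEED_WEIGHT_DOMAIN[1]), SEED_WEIGHT_DOMAIN[2])
  clamped <- h != species$height | sw != species$seed_weight
  out <- data.frame(name = species$name, height = species$height,
                    seed_weight = species$seed_weight, status = species$status,
                    clamped = clamped, stringsAsFactors = FALSE)
  weed <- virtual_weed(h, sw)
  for (s in names(scenarios)) {
    lam <- run_lifecycle(weed, scenarios[[s]], params, models)$lambda
    out[[paste0("lambda_", s)]] <- lam
    out[[paste0("viable_", s)]] <-
      if (comparator == "ge") lam >= threshold else lam > threshold
  }
  attr(out, "n_skipped") <- n_skipped
  attr(out, "threshold") <- threshold
  attr(out, "comparator") <- comparator
  class(out) <- c("species_projection", "data.frame")
  out
}

#' Viability counts and percentages by status group
#'
#' Percentages are rounded to the nearest integer (`77 = round(100*17/22)`).
#' Empty groups report `n = 0` with an undefined (`NA`) percentage.
#'
#' @param projections A `species_projection`.
#' @param scenario_name Name of the scenario column to summarise
#'   (e.g. `"high-high"`).
#' @return Data frame with columns `status`, `n`, `n_viable`, `percent`.
#' @export
viability_summary <- function(projections, scenario_name) {
  col <- paste0("viable_", scenario_name)
  if (!col %in% names(projections)) {
    wf_usage_error(sprintf("no scenario '%s' in the projection", scenario_name))
  }
  if (nrow(projections) == 0L) wf_validation_error("no projections to summarise")
  groups <- unique(projections$status)
  rows <- lapply(groups, function(g) {
    sub <- projections[projections$status == g, ]
    n <- nrow(sub); nv <- sum(sub[[col]])
    data.frame(status = g, n = n, n_viable = nv,
               percent = if (n > 0) round(100 * nv / n) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
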