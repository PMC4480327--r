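## Empirical trait -> demographic-parameter regressions.
##
## Three relationships drive the generic life-cycle model:
##   fecundity intercept : Ln(seeds per 1 g biomass) quadratic in Ln(seed wt)
##   emergence depth     : max depth (cm) linear in Ln(seed wt)
##   competition         : Ln(D5%) linear in height (cm)
## Constructors carry the published coefficient estimates as defaults; fit_*
## functions refit the same functional forms to arbitrary trait tables.

# trait domains over which the regressions were estimated; predictions are
# clamped here unless clamp = FALSE
SEED_WEIGHT_DOMAIN <- c(0.01, 20)   # mg
HEIGHT_DOMAIN <- c(10, 200)         # cm

clamp_domain <- function(x, domain, what, clamp = TRUE) {
  out_of <- x < domain[1] | x > domain[2]
  if (!any(out_of)) return(x)
  if (!clamp) return(x)
  warning(sprintf("%d %s value(s) clamped to [%g, %g]",
                  sum(out_of), what, domain[1], domain[2]), call. = FALSE)
  pmin(pmax(x, domain[1]), domain[2])
}

#' Fecundity-intercept model (quadratic in Ln seed weight)
#'
#' `y = c2 x^2 + c1 x + c0`, with `x = Ln(seed weight, mg)` and `y` the
#' intercept of the allometric fecundity relation, i.e. Ln(seeds produced by
#' 1 g of mature biomass).  Defaults are the published estimates; the
#' default quadratic is concave (`c2 <= 0`), capturing the physiological
#' ceiling on fecundity at very small seed sizes.
#'
#' @param c2,c1,c0 Polynomial coefficients.
#' @return A `fecundity_intercept_model`.
#' @export
fecundity_intercept_model <- function(c2 = -0.14, c1 = -0.70, c0 = 5.85) {
  for (v in c(c2, c1, c0)) stopifnot_scalar_number(v, "coefficient")
  structure(list(c2 = c2, c1 = c1, c0 = c0), class = "fecundity_intercept_model")
}

#' Maximum-emergence-depth model (linear in Ln seed weight)
#'
#' `depth = slope * Ln(seed weight, mg) + intercept`, floored at 0 cm.
#' The optimum emergence depth showed no significant trait relationship and
#' is treated as a constant elsewhere.
#'
#' @param slope,intercept Line coefficients (cm per Ln mg; cm).
#' @return An `emergence_depth_model`.
#' @export
emergence_depth_model <- function(slope = 1.36, intercept = 7.53) {
  stopifnot_scalar_number(slope, "slope")
  stopifnot_scalar_number(intercept, "intercept")
  structure(list(slope = slope, intercept = intercept),
            class = "emergence_depth_model")
}

#' Competition model: Ln(D5%) as a function of height
#'
#' `Ln(D5) = intercept + sign * slope_magnitude * height`.  The published
#' fit reports slope magnitude 0.020 and intercept 4.51 on the log scale.
#' The default sign is -1 so that taller weeds need fewer plants to cause a
#' 5% yield loss (D5% strictly decreasing in height), which is what the
#' fitness contours require; `sign = +1` is available as a switch.
#'
#' @param slope_magnitude Non-negative slope magnitude (per cm).
#' @param intercept Intercept on the Ln scale.
#' @param sign Either -1 (default) or +1.
#' @return A `competition_height_model`.
#' @export
competition_height_model <- function(slope_magnitude = 0.020, intercept = 4.51,
                                     sign = -1) {
  stopifnot_scalar_number(slope_magnitude, "slope_magnitude")
  stopifnot_scalar_number(intercept, "intercept")
  if (slope_magnitude < 0) wf_validation_error("`slope_magnitude` must be >= 0")
  if (!sign %in% c(-1, 1)) wf_validation_error("`sign` must be -1 or +1")
  structure(list(slope_magnitude = slope_magnitude, intercept = intercept,
                 sign = sign),
            class = "competition_height_model")
}

#' Default trait-regression models
#'
#' @return Named list with elements `fecundity`, `emergence_depth`,
#'   `competition`, each at its published default coefficients.
#' @export
default_trait_models <- function() {
  list(
    fecundity = fecundity_intercept_model(),
    emergence_depth = emergence_depth_model(),
    competition = competition_height_model()
  )
}

#' Predict the allometric fecundity intercept from seed weight
#'
#' @param seed_weight Seed weight(s) in mg, > 0.
#' @param model A `fecundity_intercept_model`.
#' @param clamp Clamp seed weight to the fitted trait domain `[0.01, 20]` mg
#'   (with a warning)?  `FALSE` allows extrapolation.
#' @return Ln(seeds produced by 1 g biomass).
#' @export
predict_fecundity_intercept <- function(seed_weight,
                                        model = fecundity_intercept_model(),
                                        clamp = TRUE) {
  if (any(!is.finite(seed_weight)) || any(seed_weight <= 0)) {
    wf_validation_error("`seed_weight` must be strictly positive")
  }
  sw <- clamp_domain(seed_weight, SEED_WEIGHT_DOMAIN, "seed weight", clamp)
  x <- log(sw)
  model$c2 * x^2 + model$c1 * x + model$c0
}

#' Predict the maximum depth of emergence from seed weight
#'
#' @inheritParams predict_fecundity_intercept
#' @param model An `emergence_depth_model`.
#' @return Depth in cm, floored at 0.
#' @export
predict_max_emergence_depth <- function(seed_weight,
                                        model = emergence_depth_model()) {
  if (any(!is.finite(seed_weight)) || any(seed_weight <= 0)) {
    wf_validation_error("`seed_weight` must be strictly positive")
  }
  pmax(0, model$slope * log(seed_weight) + model$intercept)
}

#' Predict D5% (competitive ability) from maximum height
#'
#' @param height Height(s) in cm, > 0.
#' @param model A `competition_height_model`.
#' @param clamp Clamp height to the fitted domain `[10, 200]` cm (with a
#'   warning)?  `FALSE` allows extrapolation.
#' @return Weed density (plants m^-2) causing a 5% yield loss.
#' @export
predict_d5 <- function(height, model = competition_height_model(), clamp = TRUE) {
  if (any(!is.finite(height)) || any(height <= 0)) {
    wf_validation_error("`height` must be strictly positive")
  }
  h <- clamp_domain(height, HEIGHT_DOMAIN, "height", clamp)
  exp(model$intercept + model$sign * model$slope_magnitude * h)
}

new_regression_fit <- function(coefficients, fit, n, alt = NULL,
                               quadratic_better = NA) {
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((fit$model[[1]] - mean(fit$model[[1]]))^2)
  structure(list(
    coefficients = coefficients,
    residual_variance = rss / stats::df.residual(fit),
    r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
    n = n,
    fit = fit,
    alt = alt,
    quadratic_better = quadratic_better
  ), class = "regression_fit")
}

#' Fit the fecundity-intercept quadratic
#'
#' Ordinary least squares of the fecundity intercept on Ln(seed weight) with
#' a quadratic design; the straight-line fit is computed alongside and the
#' lower-residual-variance form is flagged.
#'
#' @param seed_weight Species-mean seed weights (mg), length >= 4.
#' @param intercept Species-mean fecundity intercepts (Ln seeds per g).
#' @return A `regression_fit`; `coefficients` named `c2`, `c1`, `c0`;
#'   `quadratic_better` is `TRUE` when the quadratic has the lower residual
#'   variance.
#' @export
fit_fecundity_model <- function(seed_weight, intercept) {
  if (length(seed_weight) != length(intercept)) {
    wf_validation_error("`seed_weight` and `intercept` lengths differ")
  }
  if (length(seed_weight) < 4L) {
    wf_validation_error("at least 4 species are required to fit the quadratic")
  }
  if (any(seed_weight <= 0)) wf_validation_error("seed weights must be positive")
  x <- log(seed_weight)
  fit_q <- stats::lm(intercept ~ x + I(x^2))
  fit_l <- stats::lm(intercept ~ x)
  co <- stats::coef(fit_q)
  rv_q <- sum(stats::residuals(fit_q)^2) / stats::df.residual(fit_q)
  rv_l <- sum(stats::residuals(fit_l)^2) / stats::df.residual(fit_l)
  new_regression_fit(
    c(c2 = unname(co["I(x^2)"]), c1 = unname(co["x"]), c0 = unname(co["(Intercept)"])),
    fit_q, n = length(x), alt = fit_l, quadratic_better = rv_q < rv_l
  )
}

#' Fit a straight line, optionally on Ln(y)
#'
#' Shared fitting routine for the emergence-depth line (`y` in cm vs Ln seed
#' weight) and the competition line (Ln D5% vs height, `log_y = TRUE`).
#'
#' @param x,y Paired observations, length >= 3.
#' @param log_y Regress `Ln(y)` instead of `y` (requires `y > 0`).
#' @return A `regression_fit` with `coefficients` named `slope`, `intercept`.
#' @export
fit_loglinear_model <- function(x, y, log_y = FALSE) {
  if (length(x) != length(y)) wf_validation_error("`x` and `y` lengths differ")
  if (length(x) < 3L) wf_validation_error("at least 3 points are required")
  if (stats::var(x) == 0) wf_validation_error("`x` has zero variance")
  if (log_y) {
    if (any(y <= 0)) wf_validation_error("`log_y = TRUE` requires strictly positive y")
    y <- log(y)
  }
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  new_regression_fit(
    c(slope = unname(co["x"]), intercept = unname(co["(Intercept)"])),
    fit, n = length(x)
  )
}

#' As-model coercions from regression fits
#'
#' @param fit A `regression_fit` from the matching `fit_*` function.
#' @return The corresponding prediction model object.
#' @export
as_fecundity_model <- function(fit) {
  fecundity_intercept_model(c2 = fit$coefficients[["c2"]],
                            c1 = fit$coefficients[["c1"]],
                            c0 = fit$coefficients[["c0"]])
}

#' @rdname as_fecundity_model
#' @export
as_emergence_depth_model <- function(fit) {
  emergence_depth_model(slope = fit$coefficients[["slope"]],
                        intercept = fit$coefficients[["intercept"]])
}

#' @rdname as_fecundity_model
#' @param sign Sign convention for the competition slope (default -1).
#' @export
as_competition_model <- function(fit, sign = -1) {
  competition_height_model(slope_magnitude = abs(fit$coefficients[["slope"]]),
                           intercept = fit$coefficients[["intercept"]],
                           sign = sign)
}

#' Serialise trait models to and from JSON
#'
#' The document has keys `fecundity {c2, c1, c0}`,
#' `emergence_depth {slope, intercept}` and
#' `competition {slope_magnitude, sign, intercept}`.  The packaged file
#' `extdata/default_models.json` carries the published default coefficients.
#'
#' @param models Named list as returned by [default_trait_models()].
#' @param path JSON file path.
#' @return `write_trait_models()` returns `path` invisibly;
#'   `read_trait_models()` returns the models list.
#' @export
write_trait_models <- function(models, path) {
  doc <- list(
    fecundity = models$fecundity[c("c2", "c1", "c0")],
    emergence_depth = models$emergence_depth[c("slope", "intercept")],
    competition = models$competition[c("slope_magnitude", "sign", "intercept")]
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trait_models
#' @export
read_trait_models <- function(path) {
  if (!file.exists(path)) wf_io_error(sprintf("model file '%s' does not exist", path))
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(
    fecundity = fecundity_intercept_model(doc$fecundity$c2, doc$fecundity$c1,
                                          doc$fecundity$c0),
    emergence_depth = emergence_depth_model(doc$emergence_depth$slope,
                                            doc$emergence_depth$intercept),
    competition = competition_height_model(doc$competition$slope_magnitude,
                                           doc$competition$intercept,
                                           doc$competition$sign)
  )
}
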