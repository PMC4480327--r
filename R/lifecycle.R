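## Generic single-season life cycle of an annual weed.
##
## seedbank --emergence--> seedlings --herbicide--> mature plants
##   --hyperbolic competition--> yield loss --generic curve--> biomass
##   --allometry--> fresh seed --losses + bank decay--> seedbank at t+1
##
## lambda = seedbank(t+1) / seedbank(t) over one growing season.  Densities
## are continuous; there is no demographic stochasticity.

#' Life-cycle parameter set
#'
#' Scalar constants of the generic annual-weed model.  Defaults are the
#' published proof-of-concept values: a bank of 1000 seeds m^-2 of which a
#' median 7.1% emerge (71 seedlings m^-2), 79% of fresh seed lost to
#' predation and fatal germination, a median seedbank half-life of 1 year,
#' a crop height of 80 cm and an allometric fecundity slope fixed at 1.
#' `biomass_coeff` (g m^-2 of mature weed biomass per percent yield loss)
#' has no published value; it is set by [calibrate_biomass_coeff()] so that
#' the shortest plant in the system (10 cm) can just sustain a viable
#' population under high herbicide and high fertility by tuning seed size.
#'
#' @param initial_seedbank Seeds m^-2 at time t (> 0).
#' @param emergence_fraction Proportion of the bank emerging, in `[0, 1]`.
#' @param fresh_seed_loss Proportion of fresh seed lost, in `[0, 1]`.
#' @param seedbank_half_life Years (> 0); exponential decay rate is
#'   `Ln(2) / half_life`.
#' @param crop_height Crop canopy height, cm (> 0).
#' @param allometric_slope Slope of Ln(seed production) on Ln(biomass);
#'   fixed at 1 in the generic model.
#' @param yield_loss_cap Asymptote `m` (%) of the one-parameter hyperbola
#'   (> 5; default 100).
#' @param biomass_coeff g m^-2 biomass per % yield loss, or `NA` before
#'   calibration.
#' @param fertility_params Parameters of the default low-fertility
#'   competition coefficient: `midpoint` and `steepness` of a logistic in
#'   height relative to the crop, plus `seedweight_slope` on Ln(seed weight).
#' @param fertility_fn Optional replacement function
#'   `f(relative_height, log_seed_weight, fertility_params)` returning a
#'   multiplier in `(0, 1]`.
#' @return A `lifecycle_params` object.
#' @export
lifecycle_params <- function(initial_seedbank = 1000,
                             emergence_fraction = 0.071,
                             fresh_seed_loss = 0.79,
                             seedbank_half_life = 1,
                             crop_height = 80,
                             allometric_slope = 1,
                             yield_loss_cap = 100,
                             biomass_coeff = NA_real_,
                             fertility_params = list(midpoint = 0.25,
                                                     steepness = 5,
                                                     seedweight_slope = 0.1),
                             fertility_fn = NULL) {
  stopifnot_scalar_number(initial_seedbank, "initial_seedbank")
  if (initial_seedbank <= 0) wf_validation_error("`initial_seedbank` must be > 0")
  for (nm in c("emergence_fraction", "fresh_seed_loss")) {
    v <- get(nm)
    stopifnot_scalar_number(v, nm)
    if (v < 0 || v > 1) wf_validation_error(sprintf("`%s` must lie in [0, 1]", nm))
  }
  stopifnot_scalar_number(seedbank_half_life, "seedbank_half_life")
  if (seedbank_half_life <= 0) wf_validation_error("`seedbank_half_life` must be > 0")
  stopifnot_scalar_number(crop_height, "crop_height")
  if (crop_height <= 0) wf_validation_error("`crop_height` must be > 0")
  stopifnot_scalar_number(yield_loss_cap, "yield_loss_cap")
  if (yield_loss_cap <= 5) {
    wf_validation_error("`yield_loss_cap` must exceed 5 (the D5% definition)")
  }
  structure(list(
    initial_seedbank = initial_seedbank,
    emergence_fraction = emergence_fraction,
    fresh_seed_loss = fresh_seed_loss,
    seedbank_half_life = seedbank_half_life,
    crop_height = crop_height,
    allometric_slope = allometric_slope,
    yield_loss_cap = yield_loss_cap,
    biomass_coeff = biomass_coeff,
    fertility_params = fertility_params,
    fertility_fn = fertility_fn
  ), class = "lifecycle_params")
}

#' Management scenario
#'
#' @param herbicide_mortality Proportion of seedlings killed, in `[0, 1]`.
#'   The published scenarios use 0.96 (high) and 0.5 (low); arbitrary values
#'   are allowed for exploration.
#' @param fertility `"high"` or `"low"` fertiliser use.
#' @return A `scenario` object.
#' @export
scenario <- function(herbicide_mortality, fertility = c("high", "low")) {
  stopifnot_scalar_number(herbicide_mortality, "herbicide_mortality")
  if (herbicide_mortality < 0 || herbicide_mortality > 1) {
    wf_validation_error("`herbicide_mortality` must lie in [0, 1]")
  }
  fertility <- match.arg(fertility)
  structure(list(herbicide_mortality = herbicide_mortality,
                 fertility = fertility), class = "scenario")
}

#' The four standard management scenarios
#'
#' Named `low-low`, `low-high`, `high-low`, `high-high`
#' (herbicide-fertility), i.e. panels A-D of the fitness-contour figure.
#'
#' @return Named list of `scenario` objects.
#' @export
standard_scenarios <- function() {
  list(
    "low-low" = scenario(0.5, "low"),
    "low-high" = scenario(0.5, "high"),
    "high-low" = scenario(0.96, "low"),
    "high-high" = scenario(0.96, "high")
  )
}

#' Virtual weed defined by its two traits
#'
#' @param height Maximum height, cm (> 0); recycled against `seed_weight`.
#' @param seed_weight 1000-seed weight, mg (> 0).
#' @return A `virtual_weed` data frame (vectorised).
#' @export
virtual_weed <- function(height, seed_weight) {
  if (any(!is.finite(height)) || any(height <= 0)) {
    wf_validation_error("`height` must be strictly positive")
  }
  if (any(!is.finite(seed_weight)) || any(seed_weight <= 0)) {
    wf_validation_error("`seed_weight` must be strictly positive")
  }
  out <- data.frame(height = height, seed_weight = seed_weight)
  class(out) <- c("virtual_weed", "data.frame")
  out
}

#' Seedlings emerging from the seedbank
#'
#' @param params A `lifecycle_params`.
#' @return Seedlings m^-2 (`initial_seedbank * emergence_fraction`).
#' @export
emerge <- function(params) {
  params$initial_seedbank * params$emergence_fraction
}

#' Seedlings surviving herbicide
#'
#' Densities are kept continuous (not rounded).
#'
#' @param seedlings Seedlings m^-2 (>= 0).
#' @param scenario A `scenario`.
#' @return Plants m^-2.
#' @export
survive_herbicide <- function(seedlings, scenario) {
  if (any(seedlings < 0)) wf_validation_error("`seedlings` must be >= 0")
  m <- scenario$herbicide_mortality
  if (m < 0 || m > 1) wf_validation_error("herbicide mortality must lie in [0, 1]")
  seedlings * (1 - m)
}

#' Percent crop yield loss from surviving weeds
#'
#' The one-parameter hyperbola: the asymptote is fixed at
#' `params$yield_loss_cap` and `i` is back-solved from the trait-predicted
#' `D5%` via `i = 5 / (D5 (1 - 5/cap))`, so that a density of exactly `D5`
#' plants m^-2 returns a 5% loss by construction.
#'
#' @param survivors Plants m^-2 (>= 0).
#' @param weed A `virtual_weed` (vectorised).
#' @param comp_model A `competition_height_model`.
#' @param params A `lifecycle_params`.
#' @param clamp Clamp height to the regression domain.
#' @return List with elements `d5`, `i_param` and `yield_loss_pct`.
#' @export
yield_loss <- function(survivors, weed, comp_model = competition_height_model(),
                       params = lifecycle_params(), clamp = TRUE) {
  if (any(survivors < 0)) wf_validation_error("`survivors` must be >= 0")
  cap <- params$yield_loss_cap
  if (cap <= 5) wf_validation_error("yield-loss cap must exceed 5")
  d5 <- predict_d5(weed$height, comp_model, clamp = clamp)
  i <- 5 / (d5 * (1 - 5 / cap))
  yl <- yield_loss_hyperbolic(i, survivors, cap)
  list(d5 = d5, i_param = i, yield_loss_pct = yl)
}

# default low-fertility competition coefficient: logistic in height relative
# to the crop, shifted by Ln(seed weight); strictly inside (0, 1)
default_fertility_fn <- function(relative_height, log_seed_weight, pars) {
  stats::plogis(pars$steepness * (relative_height - pars$midpoint) +
                  pars$seedweight_slope * log_seed_weight)
}

#' Relative competitive-ability coefficient under low fertility
#'
#' At high fertility the coefficient is 1 (no adjustment).  At low fertility
#' it rescales the percent yield loss by a multiplier in `(0, 1]` that
#' increases with the weed's height relative to the crop and (by default,
#' weakly) with seed weight: tall, large-seeded weeds retain most of their
#' competitive ability when fertiliser is withheld, while short nitrophilous
#' ruderals lose most of theirs.  A user-supplied `fertility_fn` replaces
#' the default; its values are checked to lie in `(0, 1]`.
#'
#' @param weed A `virtual_weed` (vectorised).
#' @param scenario A `scenario`.
#' @param params A `lifecycle_params` (uses `crop_height`,
#'   `fertility_params`, `fertility_fn`).
#' @return Multiplier(s) in `(0, 1]`.
#' @export
fertility_coefficient <- function(weed, scenario, params = lifecycle_params()) {
  if (params$crop_height <= 0) wf_validation_error("`crop_height` must be > 0")
  n <- nrow(weed)
  if (scenario$fertility == "high") return(rep(1, n))
  fn <- params$fertility_fn
  if (is.null(fn)) fn <- default_fertility_fn
  f <- fn(weed$height / params$crop_height, log(weed$seed_weight),
          params$fertility_params)
  if (any(!is.finite(f)) || any(f <= 0) || any(f > 1)) {
    wf_validation_error("fertility coefficient must lie in (0, 1]")
  }
  f
}

#' Mature weed biomass from percent yield loss
#'
#' The generic biomass-yield-loss relationship is linear through the origin:
#' `biomass_total = biomass_coeff * yield_loss_pct`.  The coefficient is not
#' published and is normally set by [calibrate_biomass_coeff()].
#'
#' @param yield_loss_pct Percent yield loss (>= 0), after any fertility
#'   adjustment.
#' @param survivors Plants m^-2.
#' @param params A `lifecycle_params` with a finite `biomass_coeff`.
#' @return List with `biomass_total` (g m^-2) and `biomass_per_plant` (g);
#'   both zero when there are no survivors.
#' @export
biomass_from_yield_loss <- function(yield_loss_pct, survivors,
                                    params = lifecycle_params()) {
  if (any(!is.finite(params$biomass_coeff))) {
    wf_validation_error("`biomass_coeff` is not set; run calibrate_biomass_coeff()")
  }
  n <- max(length(yield_loss_pct), length(survivors))
  surv <- rep_len(survivors, n)
  total <- rep_len(params$biomass_coeff * yield_loss_pct, n)
  per_plant <- ifelse(surv > 0, total / surv, 0)
  total <- ifelse(surv > 0, total, 0)
  list(biomass_total = total, biomass_per_plant = per_plant)
}

#' Fresh seed production from the allometric relation
#'
#' Seeds per plant `= exp(a(seed_weight)) * biomass_per_plant^slope`, where
#' `a` is the trait-predicted fecundity intercept (Ln seeds per 1 g) and the
#' slope is `params$allometric_slope` (1 in the generic model, making total
#' seed production depend only on total biomass, not on how it is split
#' among plants).
#'
#' @param biomass_per_plant Grams per plant (>= 0).
#' @param survivors Plants m^-2.
#' @param weed A `virtual_weed`.
#' @param fec_model A `fecundity_intercept_model`.
#' @param params A `lifecycle_params`.
#' @param clamp Clamp seed weight to the regression domain.
#' @return Seeds m^-2.
#' @export
fecundity <- function(biomass_per_plant, survivors, weed,
                      fec_model = fecundity_intercept_model(),
                      params = lifecycle_params(), clamp = TRUE) {
  if (any(biomass_per_plant < 0)) {
    wf_validation_error("`biomass_per_plant` must be >= 0")
  }
  a <- predict_fecundity_intercept(weed$seed_weight, fec_model, clamp = clamp)
  survivors * exp(a) * biomass_per_plant^params$allometric_slope
}

#' Seedbank carry-over after germination and decay
#'
#' Germinated seed is removed first; the residual bank then decays
#' exponentially at rate `Ln(2) / half_life` over `dt` years:
#' `(bank - emerged) * exp(-Ln(2) dt / half_life)`.
#'
#' @param params A `lifecycle_params`.
#' @param emerged Seedlings m^-2 removed from the bank.
#' @param dt Years of decay (default 1, the annual cycle).
#' @return Seeds m^-2 remaining in the bank.
#' @export
seedbank_carryover <- function(params, emerged = emerge(params), dt = 1) {
  if (dt < 0) wf_validation_error("`dt` must be >= 0")
  if (any(emerged > params$initial_seedbank)) {
    wf_validation_error("emerged seedlings exceed the seedbank")
  }
  (params$initial_seedbank - emerged) * exp(-log(2) * dt / params$seedbank_half_life)
}

#' Run one annual life cycle and return lambda
#'
#' Chains [emerge()], [survive_herbicide()], [yield_loss()],
#' [fertility_coefficient()] (which multiplies the percent yield loss),
#' [biomass_from_yield_loss()], [fecundity()], fresh-seed losses and
#' [seedbank_carryover()] (dt = 1), storing every intermediate flux.
#' Vectorised over the rows of `weed`.
#'
#' @param weed A `virtual_weed` (one or more rows).
#' @param scenario A `scenario`.
#' @param params A `lifecycle_params` with `biomass_coeff` set.
#' @param models Trait models list (see [default_trait_models()]).
#' @param clamp Clamp traits to the regression domains.
#' @return A `lifecycle_result` data frame with one row per weed and columns
#'   `height`, `seed_weight`, `emerged`, `survivors`, `d5`, `i_param`,
#'   `yield_loss_pct` (raw), `fertility_coefficient`, `yield_loss_adj_pct`,
#'   `biomass_total`, `biomass_per_plant`, `seeds_produced`, `seed_rain`,
#'   `bank_carryover`, `final_seedbank`, `lambda`.
#' @export
run_lifecycle <- function(weed, scenario, params = lifecycle_params(),
                          models = default_trait_models(), clamp = TRUE) {
  emerged <- emerge(params)
  survivors <- survive_herbicide(emerged, scenario)
  yl <- yield_loss(survivors, weed, models$competition, params, clamp = clamp)
  fc <- fertility_coefficient(weed, scenario, params)
  yl_adj <- yl$yield_loss_pct * fc
  bm <- biomass_from_yield_loss(yl_adj, survivors, params)
  seeds <- fecundity(bm$biomass_per_plant, survivors, weed, models$fecundity,
                     params, clamp = clamp)
  seed_rain <- seeds * (1 - params$fresh_seed_loss)
  carry <- seedbank_carryover(params, emerged, dt = 1)
  final <- carry + seed_rain
  out <- data.frame(
    height = weed$height,
    seed_weight = weed$seed_weight,
    emerged = emerged,
    survivors = survivors,
    d5 = yl$d5,
    i_param = yl$i_param,
    yield_loss_pct = yl$yield_loss_pct,
    fertility_coefficient = fc,
    yield_loss_adj_pct = yl_adj,
    biomass_total = bm$biomass_total,
    biomass_per_plant = bm$biomass_per_plant,
    seeds_produced = seeds,
    seed_rain = seed_rain,
    bank_carryover = carry,
    final_seedbank = final,
    lambda = final / params$initial_seedbank
  )
  class(out) <- c("lifecycle_result", "data.frame")
  out
}

#' Calibrate the biomass-per-yield-loss coefficient
#'
#' Finds, by bisection, the smallest `biomass_coeff` such that the maximum
#' over seed weight of `lambda` for a 10 cm plant under high herbicide
#' mortality and high fertility equals 1: the maximum feasible stress at
#' which the shortest plant in the system can still maintain a viable
#' population by reducing seed size and increasing fecundity.
#'
#' @param params A `lifecycle_params` (its `biomass_coeff` is ignored).
#' @param models Trait models list.
#' @param tolerance Convergence tolerance on `max lambda - 1` (default 1e-8).
#' @param height Calibration height, cm (default 10, the grid minimum).
#' @param seed_weights Seed-weight grid over which the inner maximum is
#'   taken (default the sweep grid, 0.01-20 mg by 0.01).
#' @param cal_scenario Calibration scenario (default high/high).
#' @return `params` with `biomass_coeff` set; the coefficient and achieved
#'   maximum lambda are attached as attribute `"calibration"`.
#' @export
calibrate_biomass_coeff <- function(params = lifecycle_params(),
                                    models = default_trait_models(),
                                    tolerance = 1e-8,
                                    height = 10,
                                    seed_weights = seq(0.01, 20, by = 0.01),
                                    cal_scenario = scenario(0.96, "high")) {
  weed <- virtual_weed(height, seed_weights)
  max_lambda <- function(coeff) {
    p <- params
    p$biomass_coeff <- coeff
    max(run_lifecycle(weed, cal_scenario, p, models)$lambda)
  }
  lo <- 0
  if (max_lambda(lo) >= 1) {
    wf_calibration_error(
      "maximum lambda reaches 1 with zero biomass: the seedbank carry-over alone sustains the population; check half-life/emergence settings")
  }
  hi <- 1
  n_try <- 0
  while (max_lambda(hi) < 1) {
    hi <- hi * 2
    n_try <- n_try + 1
    if (n_try > 60) {
      wf_calibration_error(sprintf(
        "could not bracket the calibration target: max lambda is %.4g even at biomass_coeff = %.3g",
        max_lambda(hi), hi))
    }
  }
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    f <- max_lambda(mid)
    if (abs(f - 1) < tolerance) break
    if (f < 1) lo <- mid else hi <- mid
  }
  params$biomass_coeff <- mid
  attr(params, "calibration") <- list(
    biomass_coeff = mid, max_lambda = f, height = height,
    scenario = cal_scenario, iterations = iter
  )
  params
}
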