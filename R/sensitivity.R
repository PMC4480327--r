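## One-at-a-time multiplicative sensitivity analysis of lambda.
##
## Each registered scalar is multiplied by (1 + fraction), the life cycle is
## re-run for a baseline weed and scenario, and the percent change in lambda
## reported.  Objects are never mutated in place (R copy semantics), so
## state restoration is structural.

# registry: name -> function(params, models, scenario, fraction) returning
# the modified triple.  Proportions are capped at 1 after perturbation so a
# +5% increment on 0.96 herbicide mortality stays a valid probability.
sensitivity_registry <- function() {
  bump <- function(x, f) x * (1 + f)
  bump_prop <- function(x, f) min(1, x * (1 + f))
  list(
    fecundity_c0 = function(p, m, s, f) {
      m$fecundity$c0 <- bump(m$fecundity$c0, f); list(p, m, s)
    },
    emergence_fraction = function(p, m, s, f) {
      p$emergence_fraction <- bump_prop(p$emergence_fraction, f); list(p, m, s)
    },
    fresh_seed_loss = function(p, m, s, f) {
      p$fresh_seed_loss <- bump_prop(p$fresh_seed_loss, f); list(p, m, s)
    },
    seedbank_half_life = function(p, m, s, f) {
      p$seedbank_half_life <- bump(p$seedbank_half_life, f); list(p, m, s)
    },
    d5_intercept = function(p, m, s, f) {
      m$competition$intercept <- bump(m$competition$intercept, f); list(p, m, s)
    },
    d5_slope_magnitude = function(p, m, s, f) {
      m$competition$slope_magnitude <- bump(m$competition$slope_magnitude, f)
      list(p, m, s)
    },
    biomass_coeff = function(p, m, s, f) {
      p$biomass_coeff <- bump(p$biomass_coeff, f); list(p, m, s)
    },
    herbicide_mortality = function(p, m, s, f) {
      s$herbicide_mortality <- bump_prop(s$herbicide_mortality, f); list(p, m, s)
    },
    crop_height = function(p, m, s, f) {
      p$crop_height <- bump(p$crop_height, f); list(p, m, s)
    }
  )
}

#' Registered sensitivity parameters
#' @return Character vector of perturbable scalar names.
#' @export
sensitivity_parameters <- function() names(sensitivity_registry())

#' Perturb one parameter and report the change in lambda
#'
#' Multiplies the named scalar by `(1 + fraction)`, re-runs
#' [run_lifecycle()] for the baseline weed and scenario, and reports the
#' percent change `100 (lambda' - lambda) / lambda`.  Inputs are not
#' modified.  Perturbed proportions (herbicide mortality, emergence
#' fraction, fresh-seed loss) are capped at 1.
#'
#' @param param_name One of [sensitivity_parameters()].
#' @param weed A single-row `virtual_weed` (the baseline is an explicit
#'   input: no canonical baseline weed is defined).
#' @param scenario A `scenario`.
#' @param params Calibrated `lifecycle_params`.
#' @param models Trait models list.
#' @param fraction Perturbation fraction (default 0.05).
#' @return List with `baseline_lambda`, `perturbed_lambda`, `pct_change`.
#' @export
perturb <- function(param_name, weed, scenario, params,
                    models = default_trait_models(), fraction = 0.05) {
  reg <- sensitivity_registry()
  if (!param_name %in% names(reg)) {
    wf_usage_error(sprintf("unknown parameter '%s'; registered: %s",
                           param_name, paste(names(reg), collapse = ", ")))
  }
  base <- run_lifecycle(weed, scenario, params, models)$lambda
  mod <- reg[[param_name]](params, models, scenario, fraction)
  pert <- run_lifecycle(weed, mod[[3]], mod[[1]], mod[[2]])$lambda
  list(baseline_lambda = base, perturbed_lambda = pert,
       pct_change = 100 * (pert - base) / base)
}

#' Full one-at-a-time sensitivity report
#'
#' Applies [perturb()] to every registered parameter and ranks the rows by
#' absolute percent change in lambda.
#'
#' @inheritParams perturb
#' @return A `sensitivity_report` data frame with columns `parameter`,
#'   `baseline_lambda`, `perturbed_lambda`, `pct_change`; the baseline weed,
#'   scenario and fraction are attached as attributes.
#' @export
sensitivity_report <- function(weed, scenario, params,
                               models = default_trait_models(),
                               fraction = 0.05) {
  rows <- lapply(sensitivity_parameters(), function(nm) {
    r <- perturb(nm, weed, scenario, params, models, fraction)
    data.frame(parameter = nm, baseline_lambda = r$baseline_lambda,
               perturbed_lambda = r$perturbed_lambda,
               pct_change = r$pct_change, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-abs(out$pct_change)), ]
  rownames(out) <- NULL
  attr(out, "weed") <- weed
  attr(out, "scenario") <- scenario
  attr(out, "fraction") <- fraction
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Write a sensitivity report as delimited text
#'
#' @param report A `sensitivity_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
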