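# Independent straight-line re-implementation of the annual life cycle.
# Deliberately written as one flat formula chain from raw coefficients, not
# via the package's stage functions, so it can serve as an oracle.
oracle_lambda <- function(height, seed_weight, mortality, fertility,
                          bank = 1000, emergence = 0.071, seed_loss = 0.79,
                          half_life = 1, crop_height = 80, slope = 1,
                          cap = 100, biomass_coeff,
                          fec = c(c2 = -0.14, c1 = -0.70, c0 = 5.85),
                          comp = c(slope_magnitude = 0.020, intercept = 4.51,
                                   sign = -1),
                          fert = c(midpoint = 0.25, steepness = 5,
                                   seedweight_slope = 0.1)) {
  emerged <- bank * emergence
  surv <- emerged * (1 - mortality)
  d5 <- exp(comp[["intercept"]] + comp[["sign"]] * comp[["slope_magnitude"]] * height)
  i <- 5 / (d5 * (1 - 5 / cap))
  yl <- i * surv / (1 + i * surv / cap)
  f <- if (fertility == "high") 1 else {
    1 / (1 + exp(-(fert[["steepness"]] * (height / crop_height - fert[["midpoint"]]) +
                     fert[["seedweight_slope"]] * log(seed_weight))))
  }
  yl <- yl * f
  biomass_total <- biomass_coeff * yl
  biomass_per_plant <- if (surv > 0) biomass_total / surv else 0
  x <- log(seed_weight)
  a <- fec[["c2"]] * x^2 + fec[["c1"]] * x + fec[["c0"]]
  seeds <- if (surv > 0) surv * exp(a) * biomass_per_plant^slope else 0
  rain <- seeds * (1 - seed_loss)
  carry <- (bank - emerged) * exp(-log(2) / half_life)
  (carry + rain) / bank
}

# shared calibrated parameter set, computed once per test run
calibrated_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_biomass_coeff()
    cache
  }
})
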