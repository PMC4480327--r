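# Single-season life cycle: stages, composition, calibration.

test_that("stage arithmetic matches the published proof-of-concept numbers", {
  p <- lifecycle_params()
  expect_equal(emerge(p), 71)
  expect_equal(emerge(lifecycle_params(initial_seedbank = 500,
                                       emergence_fraction = 0.2)), 100)
  expect_equal(survive_herbicide(71, scenario(0.96)), 2.84)
  expect_equal(survive_herbicide(71, scenario(0.5)), 35.5)
  expect_equal(survive_herbicide(71, scenario(0)), 71)

  expect_equal(seedbank_carryover(p), 929 * 0.5)
  expect_equal(seedbank_carryover(p, dt = 0), 929)
  expect_equal(seedbank_carryover(lifecycle_params(seedbank_half_life = 1e12)),
               929, tolerance = 1e-9)
  expect_error(seedbank_carryover(p, emerged = 2000),
               class = "wf_validation_error")
  # half-life * decay rate = Ln(2) by construction
  hl <- 3.7
  expect_equal(hl * (log(2) / hl), log(2), tolerance = 1e-12)
})

test_that("yield loss is anchored at D5% and behaves at the edges", {
  p <- lifecycle_params()
  for (h in c(10, 55, 120, 200)) {
    d5 <- predict_d5(h)
    expect_equal(yield_loss(d5, virtual_weed(h, 1), params = p)$yield_loss_pct,
                 5, tolerance = 1e-9)
  }
  expect_equal(yield_loss(0, virtual_weed(80, 1), params = p)$yield_loss_pct, 0)
  yl <- yield_loss(35.5, virtual_weed(100, 1), params = p)
  expect_equal(yl$i_param, 5 / (yl$d5 * 0.95))
  expect_equal(yl$yield_loss_pct,
               yl$i_param * 35.5 / (1 + yl$i_param * 35.5 / 100))
  expect_lt(yl$yield_loss_pct, 100) # bounded by the cap
  expect_error(lifecycle_params(yield_loss_cap = 4),
               class = "wf_validation_error")
})

test_that("fertility coefficient: identity at high, bounded monotone at low", {
  p <- lifecycle_params()
  w <- virtual_weed(c(10, 80, 200), c(0.1, 1, 10))
  expect_equal(fertility_coefficient(w, scenario(0.96, "high"), p), rep(1, 3))

  lo <- scenario(0.5, "low")
  grid <- virtual_weed(seq(10, 200, by = 5), 1)
  f <- fertility_coefficient(grid, lo, p)
  expect_true(all(f > 0 & f <= 1))
  expect_true(all(diff(f) >= 0)) # non-decreasing in height

  p_bad <- lifecycle_params(fertility_fn = function(h, lsw, pars) rep(1.2, length(h)))
  expect_error(fertility_coefficient(w, lo, p_bad), class = "wf_validation_error")
})

test_that("biomass and fecundity stages are linear and allometric", {
  p <- lifecycle_params(biomass_coeff = 2)
  b <- biomass_from_yield_loss(13.22, 35.5, p)
  expect_equal(b$biomass_total, 26.44)
  expect_equal(b$biomass_per_plant, 26.44 / 35.5)
  expect_equal(biomass_from_yield_loss(0, 10, p)$biomass_total, 0)
  expect_equal(biomass_from_yield_loss(5, 0, p)$biomass_per_plant, 0)
  p2 <- lifecycle_params(biomass_coeff = 4)
  expect_equal(biomass_from_yield_loss(13.22, 35.5, p2)$biomass_total,
               2 * b$biomass_total)

  expect_equal(fecundity(1, 1, virtual_weed(100, 1), params = p), exp(5.85))
  expect_equal(fecundity(0, 10, virtual_weed(100, 1), params = p), 0)
  # slope 1: total seed production depends only on total biomass
  total <- 40
  for (n_plants in c(2, 8, 64)) {
    expect_equal(
      fecundity(total / n_plants, n_plants, virtual_weed(100, 1), params = p),
      exp(5.85) * total)
  }
})

test_that("run_lifecycle composes the stages and respects the fitness floor", {
  p <- lifecycle_params(biomass_coeff = 2)
  # total kill: only the bank carry-over survives
  r0 <- run_lifecycle(virtual_weed(100, 1), scenario(1, "high"), p)
  expect_equal(r0$lambda, 464.5 / 1000)
  expect_equal(r0$seeds_produced, 0)

  r <- run_lifecycle(virtual_weed(100, 1), scenario(0.5, "high"), p)
  expect_equal(r$final_seedbank, r$bank_carryover + r$seed_rain)
  expect_equal(r$lambda, r$final_seedbank / 1000)
  expect_equal(r$lambda,
               oracle_lambda(100, 1, 0.5, "high", biomass_coeff = 2),
               tolerance = 1e-12)
  expect_equal(r$lambda, 2.387, tolerance = 1e-3)

  # lambda strictly increases as mortality decreases
  lams <- sapply(seq(0, 1, by = 0.1), function(m)
    run_lifecycle(virtual_weed(100, 1), scenario(m, "high"), p)$lambda)
  expect_true(all(diff(lams) < 0))
})

test_that("run_lifecycle agrees with the independent oracle on random draws", {
  set.seed(202)
  for (k in 1:100) {
    h <- runif(1, 10, 200)
    sw <- exp(runif(1, log(0.01), log(20)))
    mort <- runif(1)
    fert <- sample(c("high", "low"), 1)
    coeff <- runif(1, 0.5, 30)
    bank <- runif(1, 100, 5000)
    emf <- runif(1, 0.01, 0.5)
    loss <- runif(1, 0.2, 0.95)
    hl <- runif(1, 0.3, 6)
    p <- lifecycle_params(initial_seedbank = bank, emergence_fraction = emf,
                          fresh_seed_loss = loss, seedbank_half_life = hl,
                          biomass_coeff = coeff)
    got <- run_lifecycle(virtual_weed(h, sw), scenario(mort, fert), p)$lambda
    want <- oracle_lambda(h, sw, mort, fert, bank = bank, emergence = emf,
                          seed_loss = loss, half_life = hl,
                          biomass_coeff = coeff)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("lambda is invariant to survivor density at fixed total biomass", {
  # allometric slope 1 identity, asserted through the oracle decomposition:
  # seed rain = (1 - loss) * exp(a) * biomass_total, independent of how the
  # biomass is split, so lambda depends on survivors only through yield loss
  p <- lifecycle_params(biomass_coeff = 7)
  set.seed(5)
  for (k in 1:20) {
    sw <- exp(runif(1, log(0.01), log(20)))
    a <- predict_fecundity_intercept(sw)
    total <- runif(1, 1, 300)
    seeds <- sapply(c(1, 5, 50), function(n)
      fecundity(total / n, n, virtual_weed(100, sw), params = p))
    expect_equal(max(seeds) - min(seeds), 0, tolerance = 1e-9 * max(seeds))
    expect_equal(seeds[1], exp(a) * total, tolerance = 1e-9)
  }
})

test_that("vectorised runs equal element-wise runs", {
  p <- calibrated_params()
  set.seed(77)
  w <- virtual_weed(runif(30, 10, 200), exp(runif(30, log(0.01), log(20))))
  for (sc in standard_scenarios()) {
    vec <- run_lifecycle(w, sc, p)$lambda
    ind <- vapply(seq_len(nrow(w)), function(k)
      run_lifecycle(w[k, ], sc, p)$lambda, numeric(1))
    expect_equal(vec, ind, tolerance = 1e-12)
  }
})

test_that("calibration pins the 10 cm plant at lambda 1 under high/high", {
  p <- calibrated_params()
  cal <- attr(p, "calibration")
  expect_equal(cal$max_lambda, 1, tolerance = 1e-6)
  sw <- seq(0.01, 20, by = 0.01)
  lam <- run_lifecycle(virtual_weed(10, sw), scenario(0.96, "high"), p)$lambda
  expect_equal(max(lam), 1, tolerance = 1e-6)

  # calibrated coefficient increases with fresh seed loss
  coeffs <- sapply(c(0.6, 0.79, 0.9), function(loss)
    calibrate_biomass_coeff(lifecycle_params(fresh_seed_loss = loss),
                            seed_weights = seq(0.01, 20, by = 0.1))$biomass_coeff)
  expect_true(all(diff(coeffs) > 0))
})
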