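{
  "params": {
    "initial_seedbank": 1000,
    "emergence_fraction": 0.071,
    "fresh_seed_loss": 0.79,
    "seedbank_half_life": 1,
    "crop_height": 80,
    "allometric_slope": 1,
    "yield_loss_cap": 100,
    "biomass_coeff": null
  },
  "fertility_params": {
    "midpoint": 0.25,
    "steepness": 5,
    "seedweight_slope": 0.1
  },
  "models": {
    "fecundity": { "c2": -0.14, "c1": -0.7, "c0": 5.85 },
    "emergence_depth": { "slope": 1.36, "intercept": 7.53 },
    "competition": { "slope_magnitude": 0.02, "sign": -1, "intercept": 4.51 }
  },
  "grid": {
    "heights": { "from": 10, "to": 200, "by": 10 },
    "seed_weights": { "from": 0.01, "to": 20, "by": 0.01 }
  },
  "viability_threshold": 1
}
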