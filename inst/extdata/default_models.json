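{
  "fecundity": { "c2": -0.14, "c1": -0.7, "c0": 5.85 },
  "emergence_depth": { "slope": 1.36, "intercept": 7.53 },
  "competition": { "slope_magnitude": 0.02, "sign": -1, "intercept": 4.51 }
}
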