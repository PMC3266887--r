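{
  "seed": 1,
  "consensus": 0.95,
  "mismatch_tolerance": 1,
  "r2_threshold": 0.5,
  "maf_min": 0.05,
  "threshold": 5e-08,
  "alphas": [0.05, 0.01, 5e-05, 5e-08],
  "recomb_prob": 0.01,
  "missing_rate": 0.01,
  "typed_fraction": 0.8,
  "scale": 0.25,
  "null_effects": false,
  "input_dir": {},
  "out_dir": {}
}
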