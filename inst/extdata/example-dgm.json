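{
  "covariate": "binary",
  "theta0_low": [0.5, 0.5], "theta0_high": [0.5, 0.5],
  "theta1_low": [0.7, 0.6], "theta1_high": [0.6, 0.55],
  "rho": 0.2, "weights": [0.75, 0.25], "n_per_arm": 300
}
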