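{
  "outcomes": ["y1", "y2"], "treatment": "treat", "covariates": ["z"],
  "weights": [0.75, 0.25], "chains": 2, "iter": 2000, "burnin": 500,
  "rules": [
    {"rule": "any"},
    {"rule": "compensatory", "weights": [0.75, 0.25]}
  ],
  "populations": [
    {"mode": "all", "name": "ATE"},
    {"mode": "fixed", "values": {"z": 0}, "name": "low"}
  ]
}
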