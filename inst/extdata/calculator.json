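{
  "coefficients": {
    "prevalence_M3": 0.833,
    "prevalence_M6": 0.079,
    "severity_M5": 0.03,
    "severity_M8": 0.035
  },
  "cutoff": 0.172,
  "epsilon": 1e-16,
  "horizon_months": 20
}
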