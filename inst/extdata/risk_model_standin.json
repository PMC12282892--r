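{
  "male": {
    "coefficients": {
      "age": 0.075,
      "sbp": 0.018,
      "tc": 0.16,
      "smoker": 0.55,
      "diabetes": 0.65
    },
    "means": {
      "age": 57,
      "sbp": 130,
      "tc": 4.9,
      "smoker": 0.45,
      "diabetes": 0
    },
    "transforms": {
      "age": "identity",
      "sbp": "identity",
      "tc": "identity",
      "smoker": "identity",
      "diabetes": "identity"
    },
    "baseline_survival_10y": 0.95,
    "recalibration_divisor": 1.59
  },
  "female": {
    "coefficients": {
      "age": 0.085,
      "sbp": 0.016,
      "tc": 0.13,
      "smoker": 0.6,
      "diabetes": 0.75
    },
    "means": {
      "age": 57,
      "sbp": 128,
      "tc": 5,
      "smoker": 0.05,
      "diabetes": 0
    },
    "transforms": {
      "age": "identity",
      "sbp": "identity",
      "tc": "identity",
      "smoker": "identity",
      "diabetes": "identity"
    },
    "baseline_survival_10y": 0.97,
    "recalibration_divisor": 1.72
  }
}
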