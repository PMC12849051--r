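{
  "model_id": "simple_rules_risk",
  "version_label": "synthetic_v1",
  "source_citation": "SYNTHETIC coefficient set: not the published simple rules risk parameters. Calibrated once to give qualitatively realistic risks on the synthetic cohort; replace via load_coefficient_set() for licensed use.",
  "transforms": {
    "b1": "identity", "b2": "identity", "b3": "identity",
    "b4": "identity", "b5": "identity",
    "m1": "identity", "m2": "identity", "m3": "identity",
    "m4": "identity", "m5": "identity",
    "oncology_centre": "identity"
  },
  "strata": {
    "all": {
      "intercept": -2.8,
      "b1": -1.4,
      "b2": -1.0,
      "b3": -1.1,
      "b4": -0.9,
      "b5": -0.9,
      "m1": 2.0,
      "m2": 1.4,
      "m3": 1.6,
      "m4": 1.9,
      "m5": 1.5,
      "oncology_centre": 0.6
    }
  }
}
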