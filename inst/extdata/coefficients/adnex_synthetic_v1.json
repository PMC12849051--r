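{
  "model_id": "adnex",
  "version_label": "synthetic_v1",
  "source_citation": "SYNTHETIC coefficient set: not the published ADNEX parameters. Calibrated once to give qualitatively realistic class probabilities on the synthetic cohort; replace via load_coefficient_set() for licensed use.",
  "transforms": {
    "age": "identity",
    "log_ca125": "log",
    "log_max_diameter": "log",
    "prop_solid": "identity",
    "more_than_10_locules": "identity",
    "papillation_count": "identity",
    "acoustic_shadows": "identity",
    "ascites": "identity",
    "oncology_centre": "identity"
  },
  "strata": {
    "borderline": {
      "intercept": -7.55,
      "age": 0.01,
      "log_ca125": 0.2,
      "log_max_diameter": 0.6,
      "prop_solid": 1.5,
      "more_than_10_locules": 0.4,
      "papillation_count": 0.35,
      "acoustic_shadows": -0.2,
      "ascites": 0.1,
      "oncology_centre": 0.3
    },
    "stage1": {
      "intercept": -9.05,
      "age": 0.02,
      "log_ca125": 0.4,
      "log_max_diameter": 0.7,
      "prop_solid": 2.5,
      "more_than_10_locules": 0.2,
      "papillation_count": 0.3,
      "acoustic_shadows": -0.3,
      "ascites": 0.5,
      "oncology_centre": 0.5
    },
    "stage2_4": {
      "intercept": -11.85,
      "age": 0.03,
      "log_ca125": 0.9,
      "log_max_diameter": 0.5,
      "prop_solid": 3.1,
      "more_than_10_locules": -0.3,
      "papillation_count": 0.2,
      "acoustic_shadows": -0.6,
      "ascites": 1.3,
      "oncology_centre": 0.7
    },
    "metastatic": {
      "intercept": -11.55,
      "age": 0.03,
      "log_ca125": 0.5,
      "log_max_diameter": 0.3,
      "prop_solid": 2.3,
      "more_than_10_locules": 0.6,
      "papillation_count": 0.1,
      "acoustic_shadows": -0.4,
      "ascites": 1.2,
      "oncology_centre": 0.4
    }
  }
}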