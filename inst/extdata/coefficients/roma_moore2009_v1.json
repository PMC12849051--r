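{
  "model_id": "roma",
  "version_label": "moore2009_v1",
  "source_citation": "Moore RG et al. Gynecol Oncol 2009;112:40-46 (predictive index for the Risk of Malignancy Algorithm, Roche assay scale)",
  "transforms": {
    "log_he4": "log",
    "log_ca125": "log"
  },
  "strata": {
    "premenopausal": {
      "intercept": -12.0,
      "log_he4": 2.38,
      "log_ca125": 0.0626
    },
    "postmenopausal": {
      "intercept": -8.09,
      "log_he4": 1.04,
      "log_ca125": 0.732
    }
  }
}
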