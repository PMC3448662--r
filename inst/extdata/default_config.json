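{
  "parameters": {
    "drug_price_is": 23,
    "drug_price_fcm": 200,
    "staff_rate": 18,
    "indirect_rate": 6,
    "device_cost": 7,
    "nonhospital_cost": 10,
    "duration_is_h": 1.25,
    "duration_fcm_h": 0.75,
    "currency_year": 2009
  },
  "bounds": {
    "drug_price_is": {"lower": 5, "upper": 23},
    "drug_price_fcm": {"lower": 80, "upper": 200},
    "staff_rate": {"lower": 12, "upper": 24},
    "indirect_rate": {"lower": 2, "upper": 10},
    "device_cost": {"lower": 5, "upper": 10},
    "nonhospital_cost": {"lower": 2, "upper": 20}
  },
  "cohort_source": "fixture",
  "seed": 1,
  "perspective": "societal",
  "psa": {
    "n_iterations": 10000,
    "distribution": "uniform",
    "seed": 1,
    "perspective": "societal"
  }
}
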