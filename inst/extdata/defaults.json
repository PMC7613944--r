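{
  "iv_naloxone": {
    "drug": "iv_naloxone",
    "dose_unit": "mg/kg",
    "half_life_min": 110,
    "half_life_sources_min": [100, 120],
    "t_measure_min": 55,
    "measurement_window_min": [45, 65],
    "t_max_min": 25,
    "affinity_ratio_dor": 41,
    "affinity_ratio_kor": 8,
    "cost": {
      "unit_label": "0.4 mg vial",
      "unit_content": 0.4,
      "unit_price_usd": [4.58, 7.07]
    }
  },
  "oral_naltrexone": {
    "drug": "oral_naltrexone",
    "dose_unit": "mg",
    "half_life_min": 4320,
    "half_life_sources_min": [4320],
    "t_measure_min": null,
    "fit_window": "within 8 h of administration",
    "t_max_min": null,
    "affinity_ratio_dor": 79,
    "affinity_ratio_kor": 2,
    "cost": {
      "unit_label": "50 mg tablet",
      "unit_content": 50,
      "unit_price_usd": [4.28, 9.72]
    }
  }
}
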