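{
  "drug": "oral_naltrexone",
  "dose": 50,
  "threshold": 90,
  "fit_window_blockade": [
    {
      "receptor": "MOR",
      "dose": 50,
      "value": 89.9546876946895
    },
    {
      "receptor": "DOR",
      "dose": 50,
      "value": 10.1812325344771
    },
    {
      "receptor": "KOR",
      "dose": 50,
      "value": 81.7433162851304
    }
  ],
  "washout_min": 21600,
  "washout_h": 360,
  "washout_days": 15,
  "cost": [
    {
      "total_drug": 50,
      "units_needed": 1,
      "cost_low": 4.28,
      "cost_high": 9.72,
      "cost_mid": 7
    }
  ]
}
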