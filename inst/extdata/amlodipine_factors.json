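[
  {"name": "U",  "low": 15.0, "mid": 17.5, "high": 20.0, "unit": "kV"},
  {"name": "MD", "low": 7.5,  "mid": 8.75, "high": 10.0, "unit": "% w/v"},
  {"name": "pH", "low": 2.0,  "mid": 3.0,  "high": 4.0,  "unit": "pH"}
]
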