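{
  "resolution": {
    "terms": ["(Intercept)", "U", "MD", "pH", "U:pH", "U^2", "pH^2"],
    "coefficient": [1.67, -0.115, 0.224, -0.156, 0.0499, -0.0720, -0.0954],
    "se": [0.0338, 0.0137, 0.0142, 0.0137, 0.0150, 0.0306, 0.0306],
    "p_value": [3.07e-11, 3.10e-5, 2.65e-7, 3.26e-6, 0.0104, 0.0464, 0.0143],
    "adj_r2": 0.974,
    "rmse": 0.0466
  },
  "time": {
    "terms": ["(Intercept)", "U", "MD", "pH", "U:pH", "pH^2"],
    "coefficient": [12.2, -2.22, 1.18, -2.59, 0.654, -1.11],
    "se": [0.256, 0.131, 0.135, 0.1303, 0.143, 0.288],
    "p_value": [3.88e-12, 3.85e-8, 1.08e-5, 9.57e-9, 0.00132, 0.00390],
    "adj_r2": 0.984,
    "rmse": 0.444
  }
}
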