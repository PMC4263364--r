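{
  "experiment": "feedforward_info",
  "seed": 1,
  "units": "bits",
  "model": {
    "eps_a": 0.01,
    "eps_m": 0.01,
    "eps_g": 0.01,
    "abar": 0.5,
    "omega_a": 1.0,
    "omega_m": 0.01
  }
}
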