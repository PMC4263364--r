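{
  "experiment": "chemotaxis_tradeoff",
  "seed": 1,
  "units": "bits",
  "model": {
    "eps_r_kT": 2.0,
    "m0": 1.0,
    "K_I_uM": 18.2,
    "K_A_uM": 3000.0,
    "dmu_kT": 6.0,
    "omega_a": 1.0,
    "omega_m": 0.01,
    "L0_uM": 94.0
  },
  "sweep": {
    "L1_min_uM": 96.0,
    "L1_max_uM": 23500.0,
    "n": 24
  }
}
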