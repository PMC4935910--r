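{
  "model": {"Lambda": 2000, "beta": 0.5, "mu": 30, "gamma": 20, "alpha": 2, "sigma": 0.02},
  "incidence": {"kind": "saturated", "params": {"omega": 0.1}},
  "simulation": {"dt": 0.001, "n_steps": 50000, "seed": 1, "n_replicates": 50, "extinction_threshold": 0.0005},
  "initial": {"S": 66.16666666666667, "I": 0.5}
}
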