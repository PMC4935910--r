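{
  "model": {"Lambda": 2000, "beta": 0.60, "mu": 11, "gamma": 13, "alpha": 2, "sigma": 0.075},
  "incidence": {"kind": "saturated", "params": {"omega": 0.1}},
  "simulation": {"dt": 0.001, "n_steps": 2000, "seed": 1, "n_replicates": 50, "extinction_threshold": 0.0005},
  "initial": {"S": 181.318181818181816, "I": 0.5}
}
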