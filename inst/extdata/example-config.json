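{
  "environment": {"c_ext": 10.5, "light": 0},
  "coculture": {"lambda_c": 1.45, "phi0": 0.5},
  "controller": {"dt_sample": 0.5},
  "run": {"mode": "closed-loop", "t_end": 30, "seed": 1, "out": "run.tsv"}
}
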