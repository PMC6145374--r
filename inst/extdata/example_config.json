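{
  "seed": 1,
  "out_dir": "runs/demo",
  "c3h": true,
  "r": 0.9,
  "scenario": "phe_label",
  "budget": 200,
  "n_static": 5,
  "lignin_tol": 0.25,
  "wall_tol": 0.5,
  "noise": {"total_sd": 0.1, "fraction_sd": 0.03, "replicates": 3}
}
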