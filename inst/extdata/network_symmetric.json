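{
  "K": [[2.0, -1.0], [-1.0, 2.0]],
  "gamma": [1.0, 1.0],
  "kBT": 1.0,
  "labels": ["sensor", "effector"],
  "comment": "symmetric two-bead benchmark: k_s = k_e = k_c = 1 kBT/nm^2, gamma = 1 kBT ps/nm^2"
}
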