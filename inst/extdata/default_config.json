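{
  "L": 10,
  "E": 5,
  "R": 2,
  "wobble_layout": null,
  "wobble_on_factor": 0.666666666666667,
  "wobble_off_factor": 1.5,
  "cut_excess": 100,
  "include_cut_x": true,
  "include_cut_y": true,
  "rates": {
    "k_off": 1,
    "k_on_inter": 0.04,
    "alpha": 1000,
    "k_on_intra": 40,
    "prebound_k_on_inter": 0.05,
    "prebound_k_off": 0.8
  }
}
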