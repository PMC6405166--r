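{
  "Src": {
    "cell_type": "RS",
    "C": 100, "v_r": -60, "v_t": -40, "v_p": 35,
    "k": 0.7, "a": 0.03, "b": -2, "c": -50, "d": 100
  },
  "Int": {
    "cell_type": "FS",
    "C": 20, "v_r": -55, "v_t": -40, "v_p": 25,
    "k": 1, "a": 0.2, "b": 0.025, "c": -45, "d": 0, "v_b": -55
  },
  "Tgt_subthreshold": {
    "cell_type": "RS",
    "C": 100, "v_r": -60, "v_t": -40, "v_p": 35,
    "k": 0.7, "a": 0.03, "b": -2, "c": -50, "d": 100
  },
  "Tgt_network": {
    "cell_type": "RS",
    "C": 50, "v_r": -60, "v_t": -45, "v_p": 35,
    "k": 0.7, "a": 0.03, "b": -2, "c": -50, "d": 100
  }
}
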