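{
  "model": ["dmc"],
  "comment": ["Synthetic stand-in generation/search bounds for DMC on the canonical seconds, sigma = 1 scale (published values rescaled from the sigma = 4, milliseconds convention). Not a transcription of any deposited table."],
  "gen": {
    "A": [0.08, 0.3],
    "tau": [0.03, 0.15],
    "mu_c": [2.5, 6.0],
    "b": [0.4, 0.7],
    "t0": [0.25, 0.4]
  },
  "search": {
    "A": [0.05, 0.35],
    "tau": [0.02, 0.2],
    "mu_c": [1.5, 7.0],
    "b": [0.3, 0.9],
    "t0": [0.15, 0.5]
  },
  "fixed": {
    "a": [2],
    "s_t0": [0.07]
  }
}
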