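{
  "model": ["rdmc"],
  "comment": ["Synthetic stand-in generation/search bounds for RDMC on the canonical seconds, sigma = 1 scale (published values rescaled from the sigma = 0.1, seconds convention). Not a transcription of any deposited table."],
  "gen": {
    "A0": [0.2, 0.85],
    "k_c": [2.0, 16.0],
    "k_i": [2.0, 16.0],
    "d_c": [2.5, 7.0],
    "d_a": [1.0, 5.0],
    "b": [0.4, 0.7],
    "t0": [0.25, 0.4]
  },
  "search": {
    "A0": [0.05, 1.0],
    "k_c": [0.5, 20.0],
    "k_i": [0.5, 20.0],
    "d_c": [1.0, 8.0],
    "d_a": [0.5, 6.0],
    "b": [0.3, 0.9],
    "t0": [0.15, 0.5]
  },
  "fixed": {
    "s_t0": [0.07]
  }
}
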