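{
  "dip4": {
    "input": [0, 0, 1, 1],
    "expected": 0.25,
    "note": "dip of equal-mass two-point data attains the 0.25 upper bound"
  },
  "dip_spread": {
    "input": [1, 2, 3, 4, 5],
    "expected": 0.1,
    "note": "equally spaced sample: dip at its 1/(2n) lower bound"
  },
  "fst_extreme": {
    "input": [0, 1],
    "expected": 1,
    "note": "one pure host of each strain: complete differentiation"
  },
  "fst_mixed": {
    "input": [0.2, 0.8, 0.5, 0.5],
    "expected": 0.18,
    "note": "population variance 0.045 over pbar(1-pbar) = 0.25"
  },
  "slide4": {
    "input": [0, 0, 3, 3],
    "expected": [0, 4.5, 0],
    "note": "window-2 sliding sample variance",
    "window_frac": 0.5
  },
  "red_fraction": {
    "input": [120, 40],
    "expected": 0.25,
    "note": "40 red of 160 total colonies"
  }
}
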