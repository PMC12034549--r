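{
  "n": 1503,
  "positive_fraction": 0.65000000000000002,
  "latent_corr": [
    [1, 0, 0, 0, 0, 0, 0, 0, 0],
    [0, 1, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.44800000000000001, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999],
    [0, 0.14999999999999999, 1, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999],
    [0, 0.14999999999999999, 0.14999999999999999, 1, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999],
    [0, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 1, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999],
    [0, 0.44800000000000001, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 1, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999],
    [0, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 1, 0.14999999999999999, 0.14999999999999999],
    [0, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 1, 0.14999999999999999],
    [0, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 0.14999999999999999, 1]
  ],
  "thresholds": [
    [-0.84162123357291418, -0.25334710313579978, 0.25334710313579978, 0.84162123357291441],
    [-0.25334710313579978, 0.52440051270804067],
    [-0.25334710313579978, 0.52440051270804067],
    [-0.25334710313579978, 0.52440051270804067],
    [-0.25334710313579978, 0.52440051270804067],
    [-0.25334710313579978, 0.52440051270804067],
    [-0.25334710313579978, 0.52440051270804067],
    [-0.25334710313579978, 0.52440051270804067],
    [-0.25334710313579978, 0.52440051270804067]
  ],
  "outcome_coefficients": [0, -2, -2, -2, -2, -2, -2, -2, -2],
  "seed": 20250414
}
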