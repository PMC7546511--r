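{
  "comment": "Synthetic template parameter set (7 isoforms, 2 conditions). Magnitudes typical of mixed-model fits to log-FPKM data; not estimated from any real dataset. varFull/varReduced are unequal-variance parameters: L residual variances then the sample random-effect variance.",
  "L": 7,
  "structure": "unequal_variance",
  "betaFull": {
    "intercept": 2.0, "cond2": 0.55,
    "iso2": -0.4, "iso3": -0.9, "iso4": -1.3, "iso5": -1.8, "iso6": -2.3, "iso7": -3.0,
    "cond2:iso2": 0.45, "cond2:iso3": -0.35, "cond2:iso4": 0.6,
    "cond2:iso5": -0.5, "cond2:iso6": 0.3, "cond2:iso7": -0.4
  },
  "betaReduced": {
    "intercept": 2.2,
    "iso2": -0.35, "iso3": -0.95, "iso4": -1.2, "iso5": -1.85, "iso6": -2.25, "iso7": -2.9
  },
  "varFull": [0.9, 0.7, 1.1, 0.8, 1.2, 1.0, 1.4, 0.25],
  "varReduced": [1.0, 0.8, 1.2, 0.9, 1.3, 1.1, 1.5, 0.3]
}
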