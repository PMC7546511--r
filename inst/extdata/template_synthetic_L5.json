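{
  "comment": "Synthetic template parameter set (5 isoforms, 2 conditions). Magnitudes typical of mixed-model fits to log-FPKM data; not estimated from any real dataset.",
  "L": 5,
  "structure": "unequal_variance",
  "betaFull": {
    "intercept": 2.3, "cond2": 0.8,
    "iso2": -0.5, "iso3": -1.1, "iso4": -1.6, "iso5": -2.2,
    "cond2:iso2": 0.55, "cond2:iso3": -0.6, "cond2:iso4": 0.7, "cond2:iso5": -0.45
  },
  "betaReduced": {
    "intercept": 2.45,
    "iso2": -0.45, "iso3": -1.05, "iso4": -1.65, "iso5": -2.15
  },
  "varFull": [0.8, 1.0, 0.7, 1.2, 0.9, 0.2],
  "varReduced": [1.0, 1.2, 0.9, 1.4, 1.1, 0.25]
}
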