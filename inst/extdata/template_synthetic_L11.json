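{
  "comment": "Synthetic template parameter set (11 isoforms, 2 conditions). Magnitudes typical of mixed-model fits to log-FPKM data; not estimated from any real dataset.",
  "L": 11,
  "structure": "unequal_variance",
  "betaFull": {
    "intercept": 1.8, "cond2": 0.7,
    "iso2": -0.3, "iso3": -0.6, "iso4": -0.9, "iso5": -1.2, "iso6": -1.5,
    "iso7": -1.9, "iso8": -2.2, "iso9": -2.6, "iso10": -3.0, "iso11": -3.4,
    "cond2:iso2": 0.5, "cond2:iso3": -0.4, "cond2:iso4": 0.6, "cond2:iso5": -0.55,
    "cond2:iso6": 0.35, "cond2:iso7": -0.3, "cond2:iso8": 0.45, "cond2:iso9": -0.5,
    "cond2:iso10": 0.3, "cond2:iso11": -0.6
  },
  "betaReduced": {
    "intercept": 1.95,
    "iso2": -0.25, "iso3": -0.55, "iso4": -0.95, "iso5": -1.15, "iso6": -1.55,
    "iso7": -1.85, "iso8": -2.25, "iso9": -2.55, "iso10": -3.05, "iso11": -3.35
  },
  "varFull": [1.1, 0.9, 1.3, 0.8, 1.0, 1.2, 0.9, 1.4, 1.0, 1.1, 1.3, 0.3],
  "varReduced": [1.25, 1.05, 1.45, 0.95, 1.15, 1.35, 1.05, 1.55, 1.15, 1.25, 1.45, 0.35]
}
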