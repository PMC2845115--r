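{
  "residue_mass": {
    "A": 313.21,
    "C": 289.18,
    "G": 329.21,
    "T": 304.2
  },
  "terminator_mass": {
    "A": 329.4,
    "C": 271.2,
    "G": 344.4,
    "T": 301.2
  },
  "terminal_adjustment": 18.02,
  "adduct_shifts": {
    "Na": 21.98,
    "K": 37.95
  },
  "min_term_gap": 8
}
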