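{
  "FP1": "frontal", "FP2": "frontal", "F3": "frontal", "F4": "frontal",
  "F7": "frontal", "F8": "frontal",
  "C3": "central", "C4": "central",
  "P3": "parietal", "P4": "parietal",
  "O1": "occipital", "O2": "occipital",
  "T3": "temporal", "T4": "temporal", "T5": "temporal", "T6": "temporal"
}
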