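{
  "EGFR": {"I": [1, 165], "II": [166, 310], "III": [311, 480], "IV": [481, 620]},
  "HER2": {"I": [1, 165], "II": [166, 310], "III": [311, 480], "IV": [481, 620]},
  "HER3": {"I": [1, 165], "II": [166, 310], "III": [311, 480], "IV": [481, 620]}
}
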