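{
  "comment": "Severity cutpoints for DASS-21 subscale scores on the doubled (0-42) scale; lower bounds, closed on the left.",
  "bands": ["normal", "mild", "moderate", "severe", "extremely severe"],
  "thresholds": {
    "depression": [0, 10, 14, 21, 28],
    "anxiety":    [0, 8, 10, 15, 20],
    "stress":     [0, 15, 19, 26, 34]
  }
}
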