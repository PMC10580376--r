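{
  "version": 1,
  "component_label": "public",
  "pgen_log10_edges": ["-Inf", -12, -9, -6, 0],
  "incidence_edges": [0, 0.02, 0.05, 0.1, 0.2, 0.3, 1],
  "row_counts": [1000, 1000, 1000, 1000],
  "rows": [
    [0.98, 0.015, 0.005, 0, 0, 0],
    [0.96, 0.025, 0.01, 0.005, 0, 0],
    [0.9, 0.06, 0.025, 0.01, 0.005, 0],
    [0.8, 0.1, 0.06, 0.03, 0.01, 0]
  ]
}
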