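{
  "n_total": 1779,
  "prevalence": 0.177065767284992,
  "seed": 1,
  "cutpoints": [-0.15, 0.75, 1.6],
  "arcs_mets": {
    "from": ["PHQ1", "PHQ2", "PHQ2", "PHQ2", "PHQ3", "PHQ4", "PHQ4", "PHQ4", "PHQ5", "PHQ5", "PHQ10"],
    "to": ["PHQ4", "PHQ1", "PHQ6", "PHQ9", "PHQ7", "PHQ3", "PHQ5", "PHQ10", "PHQ6", "PHQ7", "PHQ8"],
    "coef": [0.65, 0.65, 0.5, 0.65, 0.5, 0.65, 0.65, 0.65, 0.5, 0.5, 0.65]
  },
  "arcs_non_mets": {
    "from": ["PHQ1", "PHQ1", "PHQ1", "PHQ1", "PHQ2", "PHQ2", "PHQ2", "PHQ2", "PHQ3", "PHQ4", "PHQ4", "PHQ6", "PHQ6", "PHQ6", "PHQ6", "PHQ6", "PHQ7", "PHQ7", "PHQ8", "PHQ10", "PHQ10"],
    "to": ["PHQ2", "PHQ4", "PHQ6", "PHQ10", "PHQ3", "PHQ6", "PHQ7", "PHQ10", "PHQ5", "PHQ3", "PHQ5", "PHQ4", "PHQ7", "PHQ8", "PHQ9", "PHQ10", "PHQ5", "PHQ8", "PHQ3", "PHQ4", "PHQ7"],
    "coef": [0.65, 0.33, 0.5, 0.33, 0.33, 0.5, 0.33, 0.33, 0.33, 0.33, 0.33, 0.33, 0.33, 0.5, 0.65, 0.33, 0.33, 0.5, 0.33, 0.33, 0.33]
  }
}
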