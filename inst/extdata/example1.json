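{
  "trial_name": "multivitamins for cancer prevention",
  "design": {
    "outcome_type": "binary",
    "effect": {"type": "or", "value": 0.8},
    "additional_alternatives": [{"type": "or", "value": 0.7}],
    "alpha": 0.05,
    "planned_n_total": 15000,
    "effect_from_systematic_review": false
  },
  "n_randomised": 14641,
  "primary_predefined": false,
  "outcomes": [
    {
      "id": "total_cancer",
      "role": "primary",
      "result": {
        "measure": "HR",
        "estimate": 0.92,
        "ci_lower": 0.86,
        "ci_upper": 0.998,
        "ci_level": 0.95,
        "p": 0.04,
        "direction_of_benefit": "less_than_null"
      }
    },
    {"id": "prostate_cancer", "role": "secondary"},
    {"id": "major_cardiovascular_events", "role": "secondary"},
    {"id": "age_related_macular_degeneration", "role": "secondary"},
    {"id": "cataract", "role": "secondary"}
  ],
  "multiplicity": {"procedure": "none"},
  "bf_threshold": 0.1,
  "p_threshold": 0.05
}
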