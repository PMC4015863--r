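{
  "trial_name": "tranexamic acid in trauma with significant haemorrhage",
  "design": {
    "outcome_type": "binary",
    "control_risk": 0.20,
    "effect": {"type": "rr", "value": 0.90},
    "alpha": 0.05,
    "planned_n_total": 20000,
    "effect_from_systematic_review": false
  },
  "n_randomised": 20211,
  "outcomes": [
    {
      "id": "all_cause_mortality",
      "role": "primary",
      "timepoints_assessed": 1,
      "result": {
        "measure": "OR",
        "log_estimate": -0.12,
        "se": 0.04,
        "direction_of_benefit": "less_than_null"
      }
    }
  ],
  "bf_threshold": 0.1,
  "p_threshold": 0.05
}
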