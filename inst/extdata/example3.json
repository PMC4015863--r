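{
  "trial_name": "hydroxyethyl starch vs Ringer's acetate in severe sepsis",
  "design": {
    "outcome_type": "binary",
    "control_risk": 0.50,
    "effect": {"type": "rr", "value": 0.80},
    "alpha": 0.05,
    "power": 0.80,
    "planned_n_total": 800,
    "effect_from_systematic_review": false
  },
  "n_randomised": 804,
  "outcomes": [
    {
      "id": "death_or_end_stage_kidney_failure_90d",
      "role": "primary",
      "timepoints_assessed": 1,
      "result": {
        "events_experimental": 202,
        "n_experimental": 396,
        "events_control": 173,
        "n_control": 402
      }
    }
  ],
  "clinical": {"direction_of_benefit": "less_than_null"},
  "bf_threshold": 0.1,
  "p_threshold": 0.05
}
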