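{
  "comment": "Published summary statistics from the pooled evaluation of the two source trials: observed group summaries for selected index scores by assessment point, reported mediation products at 3 months, and the sample flow. Used as worked-example inputs and for recomputing reported derived quantities.",
  "group_summaries": [
    {"measure": "asi12", "wave": 3, "n_int": 160, "mean_int": 57.89, "sd_int": 15.08, "n_con": 112, "mean_con": 51.99, "sd_con": 12.71, "reported_d": 0.42},
    {"measure": "asi12", "wave": 6, "n_int": 117, "mean_int": 58.34, "sd_int": 14.60, "n_con": 96, "mean_con": 51.40, "sd_con": 12.28, "reported_d": 0.51},
    {"measure": "rt_frequency", "wave": 3, "n_int": 160, "mean_int": 1.47, "sd_int": 2.05, "n_con": 112, "mean_con": 0.84, "sd_con": 1.80, "reported_d": 0.32},
    {"measure": "sleep_quality", "wave": 3, "n_int": 160, "mean_int": 5.50, "sd_int": 2.19, "n_con": 112, "mean_con": 4.46, "sd_con": 2.22, "reported_d": 0.47}
  ],
  "mediation_3m": [
    {"outcome": "dass_depression", "ab": -0.31, "c": -0.56, "reported_prop_mediated": 55},
    {"outcome": "dass_anxiety", "ab": -0.11, "c": -0.32, "reported_prop_mediated": 34},
    {"outcome": "dass_stress", "ab": -0.37, "c": -0.63, "reported_prop_mediated": 59},
    {"outcome": "qol_mental", "ab": 0.53, "c": 1.09, "reported_prop_mediated": 49},
    {"outcome": "energy_fatigue", "ab": 0.85, "c": 2.00, "reported_prop_mediated": 43}
  ],
  "flow": {"baseline_n": 325, "completers_3m": 276, "reported_completion_pct": 84.9}
}
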