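{
  "comment": "Published week-8 clinical remission contingency counts for the TNFi-naive ustekinumab and adalimumab cohorts: the real head-to-head trial (SEAVUE), the primary emulated comparison, three sensitivity analyses, and the no-normalization negative control. printed_p is the p-value as printed in the source report ('-' = none printed).",
  "rows": [
    {
      "id": "seavue_published",
      "label": "Published SEAVUE results (week 8)",
      "ust_remitters": 96, "ust_n": 191,
      "ada_remitters": 93, "ada_n": 195,
      "printed_p": null
    },
    {
      "id": "primary",
      "label": "Predicted head-to-head, primary analysis",
      "ust_remitters": 67, "ust_n": 149,
      "ada_remitters": 62, "ada_n": 135,
      "printed_p": 0.9
    },
    {
      "id": "high_capture",
      "label": "Sensitivity: trials with high capture of outcomes",
      "ust_remitters": 67, "ust_n": 149,
      "ada_remitters": 60, "ada_n": 135,
      "printed_p": 1
    },
    {
      "id": "complete_case",
      "label": "Sensitivity: complete cases",
      "ust_remitters": 66, "ust_n": 148,
      "ada_remitters": 65, "ada_n": 128,
      "printed_p": 0.39
    },
    {
      "id": "information_leakage",
      "label": "Sensitivity: information leakage",
      "ust_remitters": 67, "ust_n": 149,
      "ada_remitters": 67, "ada_n": 135,
      "printed_p": 0.47
    },
    {
      "id": "negative_control",
      "label": "Negative control, no normalization",
      "ust_remitters": 67, "ust_n": 149,
      "ada_remitters": 119, "ada_n": 239,
      "printed_p": 0.4
    }
  ]
}
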