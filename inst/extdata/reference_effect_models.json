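{
  "comment": "Published reference coefficient tables for the placebo-attributable and adalimumab-attributable trial-random-intercept models (week-8 CDAI reduction, centered covariates). p-values printed as '<0.001' are stored as 0.001. Variance components were not published; only the ICC is recorded.",
  "placebo": {
    "outcome_label": "placebo_effect",
    "include_year": true,
    "coefficients": {
      "intercept": 92.18,
      "year_c": -1.89,
      "baseline_cdai_c": 0.37,
      "age_c": 0.13,
      "bmi_c": 0.52,
      "crp_c": -0.28,
      "sex_male": -0.72,
      "tnfi_history": -37.56,
      "steroid_use": 7.15,
      "immunomodulator_use": 5.42,
      "ileal_disease": -7.46
    },
    "standard_errors": {
      "intercept": 13.12,
      "year_c": 1.55,
      "baseline_cdai_c": 0.04,
      "age_c": 0.21,
      "bmi_c": 0.54,
      "crp_c": 0.11,
      "sex_male": 5.17,
      "tnfi_history": 6.32,
      "steroid_use": 5.24,
      "immunomodulator_use": 5.45,
      "ileal_disease": 5.99
    },
    "p_values": {
      "intercept": 0.001,
      "year_c": 0.223,
      "baseline_cdai_c": 0.001,
      "age_c": 0.549,
      "bmi_c": 0.341,
      "crp_c": 0.012,
      "sex_male": 0.889,
      "tnfi_history": 0.001,
      "steroid_use": 0.172,
      "immunomodulator_use": 0.32,
      "ileal_disease": 0.213
    },
    "random_intercepts": {
      "PRECISE1": -12.808,
      "UNITI1": -7.975,
      "CERTIFI": -6.328,
      "ENACT": 6.077,
      "ENCORE": 8.669,
      "UNITI2": 12.366
    },
    "icc": 0.02,
    "n_obs": 1310,
    "n_trials": 6,
    "method": "fixture"
  },
  "adalimumab": {
    "outcome_label": "drug_attributable:ADA",
    "include_year": false,
    "coefficients": {
      "intercept": 67.57,
      "baseline_cdai_c": 0.12,
      "age_c": -1.77,
      "bmi_c": -1.45,
      "crp_c": -0.35,
      "sex_male": 7.14,
      "tnfi_history": 7.51,
      "steroid_use": 5.36,
      "immunomodulator_use": -17.43,
      "ileal_disease": 32.84
    },
    "standard_errors": {
      "intercept": 20.41,
      "baseline_cdai_c": 0.11,
      "age_c": 0.57,
      "bmi_c": 1.34,
      "crp_c": 0.28,
      "sex_male": 12.13,
      "tnfi_history": 20.38,
      "steroid_use": 14.35,
      "immunomodulator_use": 12.54,
      "ileal_disease": 13.74
    },
    "p_values": {
      "intercept": 0.001,
      "baseline_cdai_c": 0.276,
      "age_c": 0.002,
      "bmi_c": 0.28,
      "crp_c": 0.213,
      "sex_male": 0.556,
      "tnfi_history": 0.712,
      "steroid_use": 0.709,
      "immunomodulator_use": 0.164,
      "ileal_disease": 0.836
    },
    "random_intercepts": {
      "CLASSIC": -20.215,
      "EXTEND": 9.439,
      "NCT02499783": 10.775
    },
    "icc": 0.05,
    "n_obs": 239,
    "n_trials": 3,
    "method": "fixture"
  }
}
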