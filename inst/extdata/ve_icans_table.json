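{
  "features": {
    "delta_le1": 10,
    "delta_1_2": 6,
    "delta_2_3": 5,
    "delta_3_4": 3,
    "theta_4_5": 2,
    "theta_5_6": 1,
    "theta_6_8": 1,
    "alpha_ge9": -1,
    "pdr": -1,
    "grda": 2,
    "gpds": 2,
    "low_voltage_moderate": 2
  },
  "severe": ["ncse", "low_voltage_extreme", "burst_suppression", "unreactive_eeg"],
  "max_score": 18,
  "vocabulary_version": "table2-1hz-bins-v1",
  "note": "Published VE-ICANS grading system"
}
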