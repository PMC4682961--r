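{
  "schema_version": 1,
  "myocyte": {
    "base_model": "ORd2011-endo + TP06 INa",
    "membrane_capacitance_pF": 185,
    "conductance_multipliers": {
      "control": {},
      "type-I": {"I_CaL": 4, "I_Kr": 0.21},
      "type-II": {"I_CaL": 4, "I_Kr": 0.12}
    }
  },
  "fibroblast": {
    "capacitance_pF": 6.3,
    "conductance_nS": 4,
    "piecewise_conductance_nS": [2, 4],
    "piecewise_breakpoint_mV": -20,
    "gap_conductance_nS": 8
  },
  "tissue": {
    "dx_cm": 0.02,
    "dt_ms": 0.02,
    "D0_cm2_per_ms": 0.0012,
    "domain_sites": [448, 448],
    "duration_ms": 15000
  },
  "stimulus": {
    "tissue": {"amplitude_uA_per_uF": -150, "duration_ms": 3,
               "region_cm": [3, 0.14], "placement": "lower-right",
               "pcl_ms": 1000, "first_ms": 50},
    "cell": {"amplitude_uA_per_uF": -80, "duration_ms": 0.5,
             "pcl_ms": 1000, "first_ms": 50}
  },
  "analysis": {
    "upstroke_threshold_mV": -40,
    "repolarization_fraction": 0.9,
    "ead_prominence_mV": 1,
    "type2_elevation_margin_mV": 10,
    "pvc_merge_ms": 50,
    "spectrum_window_s": 10,
    "quasiperiodic_tolerance": 0.02,
    "quasiperiodic_max_order": 4
  }
}
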