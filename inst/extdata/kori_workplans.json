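{
  "note": "Work plans reconstructed from the printed per-task tables. dose_rate_msv_h values are the published point-kernel results; durations in minutes. uncertainty_fraction is back-derived from each printed max work time (max/total - 1). repetitions back-derived from the printed collective times.",
  "worker_distance_cm": {"cutter": [30, 38], "rpo": [100, 130]},
  "plans": [
    {
      "label": "upper_fragmentation", "part": "upper", "process": "fragmentation",
      "repetitions": 6, "uncertainty_fraction": 0.038,
      "tasks": [
        {"label": "Cutter 1", "role": "cutter", "duration_min": 135, "dose_rate_msv_h": 1.30e1},
        {"label": "Cutter 2", "role": "cutter", "duration_min": 165, "dose_rate_msv_h": 8.30e-4},
        {"label": "Cutter 3", "role": "cutter", "duration_min": 129, "dose_rate_msv_h": 7.50e0},
        {"label": "Cutter 4", "role": "cutter", "duration_min": 172, "dose_rate_msv_h": 7.00e0},
        {"label": "Cutter 5", "role": "cutter", "duration_min": 165, "dose_rate_msv_h": 7.60e-4},
        {"label": "Cutter 6", "role": "cutter", "duration_min": 182, "dose_rate_msv_h": 1.10e1},
        {"label": "RPO 1",    "role": "rpo",    "duration_min": 948, "dose_rate_msv_h": 8.80e-4}
      ]
    },
    {
      "label": "active_fragmentation", "part": "active", "process": "fragmentation",
      "repetitions": 6, "uncertainty_fraction": 0.03956,
      "tasks": [
        {"label": "Cutter_7",  "role": "cutter", "duration_min": 165, "dose_rate_msv_h": 5.70e2},
        {"label": "Cutter_8",  "role": "cutter", "duration_min": 172, "dose_rate_msv_h": 3.10e1},
        {"label": "Cutter_9",  "role": "cutter", "duration_min": 182, "dose_rate_msv_h": 2.10e1},
        {"label": "Cutter_10", "role": "cutter", "duration_min": 165, "dose_rate_msv_h": 3.20e2},
        {"label": "Cutter_11", "role": "cutter", "duration_min": 129, "dose_rate_msv_h": 1.90e1},
        {"label": "Cutter_12", "role": "cutter", "duration_min": 135, "dose_rate_msv_h": 8.10e1},
        {"label": "RPO 2",     "role": "rpo",    "duration_min": 948, "dose_rate_msv_h": 2.60e-2}
      ]
    },
    {
      "label": "lower_fragmentation", "part": "lower", "process": "fragmentation",
      "repetitions": 8, "uncertainty_fraction": 0.03613,
      "tasks": [
        {"label": "Cutter_13", "role": "cutter", "duration_min": 129, "dose_rate_msv_h": 1.20e1},
        {"label": "Cutter_14", "role": "cutter", "duration_min": 165, "dose_rate_msv_h": 1.20e-2},
        {"label": "Cutter_15", "role": "cutter", "duration_min": 135, "dose_rate_msv_h": 7.80e0},
        {"label": "Cutter_16", "role": "cutter", "duration_min": 182, "dose_rate_msv_h": 9.30e0},
        {"label": "Cutter_17", "role": "cutter", "duration_min": 165, "dose_rate_msv_h": 7.00e-3},
        {"label": "Cutter_18", "role": "cutter", "duration_min": 172, "dose_rate_msv_h": 1.40e1},
        {"label": "RPO_3",     "role": "rpo",    "duration_min": 948, "dose_rate_msv_h": 1.30e-2}
      ]
    },
    {
      "label": "upper_segmentation", "part": "upper", "process": "segmentation",
      "repetitions": 6, "uncertainty_fraction": 0.0058,
      "tasks": [
        {"label": "cutter_1", "role": "cutter", "duration_min": 220,  "dose_rate_msv_h": 3.80e0},
        {"label": "cutter_2", "role": "cutter", "duration_min": 300,  "dose_rate_msv_h": 4.20e0},
        {"label": "cutter_3", "role": "cutter", "duration_min": 260,  "dose_rate_msv_h": 8.90e0},
        {"label": "cutter_4", "role": "cutter", "duration_min": 200,  "dose_rate_msv_h": 8.40e0},
        {"label": "cutter_5", "role": "cutter", "duration_min": 185,  "dose_rate_msv_h": 4.40e0},
        {"label": "cutter_6", "role": "cutter", "duration_min": 240,  "dose_rate_msv_h": 2.70e0},
        {"label": "RPO",      "role": "rpo",    "duration_min": 1405, "dose_rate_msv_h": 1.40e0}
      ]
    },
    {
      "label": "active_segmentation", "part": "active", "process": "segmentation",
      "repetitions": 6, "uncertainty_fraction": 0.009537,
      "tasks": [
        {"label": "cutter_1", "role": "cutter", "duration_min": 260,  "dose_rate_msv_h": 3.60e1},
        {"label": "cutter_2", "role": "cutter", "duration_min": 200,  "dose_rate_msv_h": 3.50e1},
        {"label": "cutter_3", "role": "cutter", "duration_min": 220,  "dose_rate_msv_h": 2.70e1},
        {"label": "cutter_4", "role": "cutter", "duration_min": 185,  "dose_rate_msv_h": 4.10e1},
        {"label": "cutter_5", "role": "cutter", "duration_min": 300,  "dose_rate_msv_h": 3.60e1},
        {"label": "cutter_6", "role": "cutter", "duration_min": 240,  "dose_rate_msv_h": 3.60e1},
        {"label": "RPO 1",    "role": "rpo",    "duration_min": 1405, "dose_rate_msv_h": 9.20e0}
      ]
    },
    {
      "label": "lower_segmentation", "part": "lower", "process": "segmentation",
      "repetitions": 8, "uncertainty_fraction": 0.009964,
      "tasks": [
        {"label": "Cutter_1", "role": "cutter", "duration_min": 185,  "dose_rate_msv_h": 4.20e0},
        {"label": "Cutter_2", "role": "cutter", "duration_min": 260,  "dose_rate_msv_h": 8.00e0},
        {"label": "Cutter_3", "role": "cutter", "duration_min": 220,  "dose_rate_msv_h": 4.00e0},
        {"label": "Cutter_4", "role": "cutter", "duration_min": 200,  "dose_rate_msv_h": 2.10e0},
        {"label": "Cutter_5", "role": "cutter", "duration_min": 240,  "dose_rate_msv_h": 1.50e0},
        {"label": "Cutter_6", "role": "cutter", "duration_min": 300,  "dose_rate_msv_h": 1.40e0},
        {"label": "RPO",      "role": "rpo",    "duration_min": 1405, "dose_rate_msv_h": 5.60e-1}
      ]
    }
  ]
}
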