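{
  "note": "Cutting-scenario parameters. Printed cut lengths are authoritative for cutting times (the published arithmetic uses pi = 3.14 and mixed 0.01/0.1 m rounding). radial_cut_length_m is the printed 21.08 m, not 0.68*32 = 21.76 m; the inconsistency is retained as published.",
  "rpv": {
    "total_height_m": 14.67, "body_length_m": 12.4, "inside_diameter_m": 4.17,
    "shell_thickness_m": 0.26, "outside_diameter_m": 4.7, "cap_length_m": 2.27,
    "leg_fragment_height_m": 0.68
  },
  "drum": {"height_m": 0.8, "diameter_m": 0.57},
  "counts": {
    "body_fragments": 18, "body_segments_per_fragment": 32,
    "cap_fragments": 4, "cap_top_segments": 32, "cap_small_segments": 10,
    "leg_cuts": 6, "published_total_pieces": 664
  },
  "cut_lengths_m": {
    "body_circumference": 14.76,
    "cap_top_circumference": 7.4,
    "cap_small_circumference": 3.69,
    "radial_cut_length": 21.08
  },
  "scenario_speed_mm_min": 15,
  "technologies": [
    {"name": "waterjet", "speed_mm_min": 85, "speed_range_mm_min": [70, 100], "max_thickness_cm": 20},
    {"name": "laser", "speed_mm_min": 100, "speed_range_mm_min": [15, 45], "max_thickness_cm": 20,
     "note": "table lists 15-45; the sensitivity text uses 100 for laser"},
    {"name": "shear", "speed_mm_min": 30, "speed_range_mm_min": [15, 50], "max_thickness_cm": 20},
    {"name": "plasma", "speed_mm_min": 15, "speed_range_mm_min": [150, 150], "max_thickness_cm": 20,
     "note": "table lists 150; every worked calculation and the sensitivity text use 15"}
  ]
}
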