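{
  "note": "RPV of the Kori-1 fixture: cylindrical body shell (12.4 m) split into lower/active/upper axial zones of equal height, plus a bottom spherical-cap shell (2.27 m cap length). Homogeneous stainless steel shell (the body/cladding split is not published). Legs appear in the cut plan only. Units: metres.",
  "ambient": "air",
  "regions": [
    {
      "name": "lower_shell", "material": "stainless_steel", "priority": 1,
      "shape": {"type": "cylinder_shell", "base": [0, 0, 0], "axis": [0, 0, 1],
                "r_inner": 2.085, "r_outer": 2.35, "height": 4.1333}
    },
    {
      "name": "active_shell", "material": "stainless_steel", "priority": 1,
      "shape": {"type": "cylinder_shell", "base": [0, 0, 4.1333], "axis": [0, 0, 1],
                "r_inner": 2.085, "r_outer": 2.35, "height": 4.1333}
    },
    {
      "name": "upper_shell", "material": "stainless_steel", "priority": 1,
      "shape": {"type": "cylinder_shell", "base": [0, 0, 8.2667], "axis": [0, 0, 1],
                "r_inner": 2.085, "r_outer": 2.35, "height": 4.1333}
    },
    {
      "name": "bottom_cap_shell", "material": "stainless_steel", "priority": 1,
      "shape": {"type": "sphere_shell", "center": [0, 0, 0], "axis": [0, 0, 1],
                "r_inner": 2.085, "r_outer": 2.35, "h_range": [-2.35, -0.08]}
    }
  ],
  "dimensions": {
    "total_height_m": 14.67, "body_length_m": 12.4, "inside_diameter_m": 4.17,
    "shell_thickness_m": 0.26, "outside_diameter_m": 4.7, "cap_length_m": 2.27,
    "leg_fragment_height_m": 0.68
  }
}
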