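material,energy_mev,b,c,a,xk,d,note
carbon_steel,0.05,1.077,0.45,0.22,14.0,0.05,approximate GP fit (iron)
carbon_steel,0.10,1.193,0.65,0.15,14.0,0.02,approximate GP fit (iron)
carbon_steel,0.20,1.348,0.79,0.11,13.5,0.01,approximate GP fit (iron)
carbon_steel,0.30,1.425,0.86,0.09,13.5,0.00,approximate GP fit (iron)
carbon_steel,0.50,1.479,0.91,0.07,13.3,-0.01,approximate GP fit (iron)
carbon_steel,1.00,1.417,0.97,0.05,13.1,-0.02,approximate GP fit (iron)
carbon_steel,2.00,1.301,1.01,0.03,13.0,-0.02,approximate GP fit (iron)
carbon_steel,3.00,1.232,1.02,0.02,13.0,-0.02,approximate GP fit (iron)
stainless_steel,0.05,1.077,0.45,0.22,14.0,0.05,approximate GP fit (iron)
stainless_steel,0.10,1.193,0.65,0.15,14.0,0.02,approximate GP fit (iron)
stainless_steel,0.20,1.348,0.79,0.11,13.5,0.01,approximate GP fit (iron)
stainless_steel,0.30,1.425,0.86,0.09,13.5,0.00,approximate GP fit (iron)
stainless_steel,0.50,1.479,0.91,0.07,13.3,-0.01,approximate GP fit (iron)
stainless_steel,1.00,1.417,0.97,0.05,13.1,-0.02,approximate GP fit (iron)
stainless_steel,2.00,1.301,1.01,0.03,13.0,-0.02,approximate GP fit (iron)
stainless_steel,3.00,1.232,1.02,0.02,13.0,-0.02,approximate GP fit (iron)
water,0.05,1.386,0.35,0.30,14.0,0.04,approximate GP fit
water,0.10,1.695,0.65,0.19,14.0,0.02,approximate GP fit
water,0.20,1.850,0.85,0.13,14.0,0.00,approximate GP fit
water,0.30,1.811,0.92,0.10,13.8,-0.01,approximate GP fit
water,0.50,1.695,0.98,0.08,13.5,-0.02,approximate GP fit
water,1.00,1.564,1.03,0.06,13.2,-0.03,approximate GP fit
water,2.00,1.386,1.06,0.04,13.0,-0.03,approximate GP fit
water,3.00,1.290,1.07,0.03,13.0,-0.03,approximate GP fit
air,0.05,1.309,0.35,0.30,14.0,0.04,approximate GP fit (water-like)
air,0.10,1.618,0.65,0.19,14.0,0.02,approximate GP fit (water-like)
air,0.20,1.773,0.85,0.13,14.0,0.00,approximate GP fit (water-like)
air,0.30,1.734,0.92,0.10,13.8,-0.01,approximate GP fit (water-like)
air,0.50,1.618,0.98,0.08,13.5,-0.02,approximate GP fit (water-like)
air,1.00,1.487,1.03,0.06,13.2,-0.03,approximate GP fit (water-like)
air,2.00,1.348,1.06,0.04,13.0,-0.03,approximate GP fit (water-like)
air,3.00,1.251,1.07,0.03,13.0,-0.03,approximate GP fit (water-like)
concrete,0.05,1.193,0.40,0.25,14.0,0.04,approximate GP fit
concrete,0.10,1.464,0.65,0.17,14.0,0.02,approximate GP fit
concrete,0.20,1.695,0.83,0.12,13.8,0.00,approximate GP fit
concrete,0.30,1.734,0.90,0.10,13.6,-0.01,approximate GP fit
concrete,0.50,1.657,0.96,0.08,13.4,-0.02,approximate GP fit
concrete,1.00,1.529,1.02,0.06,13.1,-0.03,approximate GP fit
concrete,2.00,1.367,1.05,0.04,13.0,-0.03,approximate GP fit
concrete,3.00,1.278,1.06,0.03,13.0,-0.03,approximate GP fit
lead,0.10,1.039,0.40,0.20,14.0,0.05,approximate GP fit
lead,0.20,1.108,0.65,0.15,14.0,0.03,approximate GP fit
lead,0.30,1.174,0.80,0.12,14.0,0.02,approximate GP fit
lead,0.50,1.267,0.90,0.10,13.8,0.01,approximate GP fit
lead,1.00,1.386,1.00,0.07,13.4,-0.01,approximate GP fit
lead,2.00,1.425,1.06,0.05,13.2,-0.02,approximate GP fit
lead,3.00,1.406,1.10,0.04,13.0,-0.03,approximate GP fit
vacuum,0.01,1.000,1.00,0.00,13.0,0.00,no build-up in vacuum
vacuum,3.00,1.000,1.00,0.00,13.0,0.00,no build-up in vacuum
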