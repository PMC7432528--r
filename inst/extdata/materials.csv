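material,density_g_cm3,note
air,0.001205,dry air near sea level
water,1.000,liquid water
carbon_steel,7.85,iron attenuation curve
stainless_steel,7.90,iron attenuation curve
concrete,2.30,ordinary concrete
lead,11.35,elemental lead
vacuum,1e-20,numerical vacuum for analytic toy cases
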