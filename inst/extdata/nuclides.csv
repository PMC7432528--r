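nuclide,half_life_value,half_life_unit,half_life_years,corrected_half_life_years,note
Fe-55,2.74,years,2.74,2.74,"inventory table; EC decay, 5.9 keV X-rays only, no gamma lines in library"
Co-60,5.27,years,5.27,5.27,inventory table
Eu-152,13.52,years,13.52,13.52,inventory table
Eu-154,8.59,years,8.59,8.59,inventory table
Cs-134,2.06,years,2.06,2.06,inventory table
Eu-155,4.76,years,4.76,4.76,inventory table
Ag-110m,250,days,0.6845,0.6845,inventory table
Tc-99,6,hours,0.000684,211100,"inventory table prints 6 hours (physically wrong; Tc-99m confusion); corrected ground-state value 2.111e5 y available via use_corrected_half_lives"
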