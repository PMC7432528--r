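part,nuclide,activity_bq,provenance
active,Fe-55,6.96e14,source-term table row 1
active,Co-60,2.23e12,source-term table row 2
active,Eu-152,6.62e9,source-term table row 3
active,Eu-154,1.23e9,source-term table row 4
active,Cs-134,2.60e8,source-term table row 5
active,Eu-155,3.76e7,source-term table row 6
active,Ag-110m,3.28e5,source-term table row 7
active,Tc-99,2.35e4,source-term table row 8
upper,Fe-55,1.28e13,source-term table row 1
upper,Co-60,3.52e10,source-term table row 2
upper,Eu-152,1.75e8,source-term table row 3
upper,Eu-154,2.35e7,source-term table row 4
upper,Cs-134,4.69e6,source-term table row 5
upper,Eu-155,3.16e5,source-term table row 6
upper,Ag-110m,3.75e3,source-term table row 7
upper,Tc-99,3.96e2,source-term table row 8
lower,Fe-55,3.56e9,source-term table row 1
lower,Co-60,5.25e6,source-term table row 2
lower,Eu-152,1.56e4,source-term table row 3
lower,Eu-154,1.65e3,source-term table row 4
lower,Cs-134,9.08e2,source-term table row 5
lower,Eu-155,1.50e1,source-term table row 6
lower,Ag-110m,3.43e0,source-term table row 7
lower,Tc-99,1.43e-2,source-term table row 8
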