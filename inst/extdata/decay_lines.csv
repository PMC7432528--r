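nuclide,energy_mev,yield,note
Co-60,1.17323,0.9985,standard decay-data compilation
Co-60,1.33249,0.99983,standard decay-data compilation
Eu-152,0.12178,0.2853,standard decay-data compilation
Eu-152,0.24470,0.0755,standard decay-data compilation
Eu-152,0.34428,0.2659,standard decay-data compilation
Eu-152,0.41112,0.02237,standard decay-data compilation
Eu-152,0.44397,0.02827,standard decay-data compilation
Eu-152,0.77890,0.1293,standard decay-data compilation
Eu-152,0.86738,0.0423,standard decay-data compilation
Eu-152,0.96408,0.1451,standard decay-data compilation
Eu-152,1.08587,0.1011,standard decay-data compilation
Eu-152,1.08990,0.01734,standard decay-data compilation
Eu-152,1.11207,0.1367,standard decay-data compilation
Eu-152,1.21295,0.01415,standard decay-data compilation
Eu-152,1.29914,0.01633,standard decay-data compilation
Eu-152,1.40801,0.2087,standard decay-data compilation
Eu-154,0.12307,0.404,standard decay-data compilation
Eu-154,0.24769,0.0689,standard decay-data compilation
Eu-154,0.59175,0.0495,standard decay-data compilation
Eu-154,0.69251,0.0180,standard decay-data compilation
Eu-154,0.72330,0.2005,standard decay-data compilation
Eu-154,0.75650,0.0453,standard decay-data compilation
Eu-154,0.87318,0.1217,standard decay-data compilation
Eu-154,0.99626,0.1050,standard decay-data compilation
Eu-154,1.00476,0.1790,standard decay-data compilation
Eu-154,1.24614,0.00862,standard decay-data compilation
Eu-154,1.27443,0.3490,standard decay-data compilation
Eu-154,1.59648,0.0180,standard decay-data compilation
Cs-134,0.47536,0.0149,standard decay-data compilation
Cs-134,0.56325,0.0835,standard decay-data compilation
Cs-134,0.56928,0.1539,standard decay-data compilation
Cs-134,0.60472,0.9762,standard decay-data compilation
Cs-134,0.79586,0.8546,standard decay-data compilation
Cs-134,0.80193,0.0871,standard decay-data compilation
Cs-134,1.03860,0.00990,standard decay-data compilation
Cs-134,1.16796,0.01790,standard decay-data compilation
Cs-134,1.36516,0.03017,standard decay-data compilation
Eu-155,0.06001,0.0122,standard decay-data compilation
Eu-155,0.08655,0.307,standard decay-data compilation
Eu-155,0.10532,0.211,standard decay-data compilation
Ag-110m,0.44637,0.0370,standard decay-data compilation
Ag-110m,0.62036,0.0273,standard decay-data compilation
Ag-110m,0.65776,0.9461,standard decay-data compilation
Ag-110m,0.67762,0.1056,standard decay-data compilation
Ag-110m,0.68702,0.0653,standard decay-data compilation
Ag-110m,0.70682,0.1644,standard decay-data compilation
Ag-110m,0.74436,0.0472,standard decay-data compilation
Ag-110m,0.76394,0.2231,standard decay-data compilation
Ag-110m,0.81846,0.0731,standard decay-data compilation
Ag-110m,0.88468,0.7268,standard decay-data compilation
Ag-110m,0.93749,0.3426,standard decay-data compilation
Ag-110m,1.38429,0.2473,standard decay-data compilation
Ag-110m,1.47580,0.0399,standard decay-data compilation
Ag-110m,1.50503,0.1311,standard decay-data compilation
Ag-110m,1.56230,0.0121,standard decay-data compilation
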