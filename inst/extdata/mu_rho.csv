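material,energy_mev,mu_over_rho_cm2_g,note
air,0.010,5.120,XCOM-style compilation
air,0.015,1.614,XCOM-style compilation
air,0.020,0.7779,XCOM-style compilation
air,0.030,0.3538,XCOM-style compilation
air,0.040,0.2485,XCOM-style compilation
air,0.050,0.2080,XCOM-style compilation
air,0.060,0.1875,XCOM-style compilation
air,0.080,0.1662,XCOM-style compilation
air,0.100,0.1541,XCOM-style compilation
air,0.150,0.1356,XCOM-style compilation
air,0.200,0.1233,XCOM-style compilation
air,0.300,0.1067,XCOM-style compilation
air,0.400,0.09549,XCOM-style compilation
air,0.500,0.08712,XCOM-style compilation
air,0.600,0.08055,XCOM-style compilation
air,0.800,0.07074,XCOM-style compilation
air,1.000,0.06358,XCOM-style compilation
air,1.250,0.05687,XCOM-style compilation
air,1.500,0.05175,XCOM-style compilation
air,2.000,0.04447,XCOM-style compilation
air,3.000,0.03581,XCOM-style compilation
water,0.010,5.329,XCOM-style compilation
water,0.015,1.673,XCOM-style compilation
water,0.020,0.8096,XCOM-style compilation
water,0.030,0.3756,XCOM-style compilation
water,0.040,0.2683,XCOM-style compilation
water,0.050,0.2269,XCOM-style compilation
water,0.060,0.2059,XCOM-style compilation
water,0.080,0.1837,XCOM-style compilation
water,0.100,0.1707,XCOM-style compilation
water,0.150,0.1505,XCOM-style compilation
water,0.200,0.1370,XCOM-style compilation
water,0.300,0.1186,XCOM-style compilation
water,0.400,0.1061,XCOM-style compilation
water,0.500,0.09687,XCOM-style compilation
water,0.600,0.08956,XCOM-style compilation
water,0.800,0.07865,XCOM-style compilation
water,1.000,0.07072,XCOM-style compilation
water,1.250,0.06323,XCOM-style compilation
water,1.500,0.05754,XCOM-style compilation
water,2.000,0.04942,XCOM-style compilation
water,3.000,0.03969,XCOM-style compilation
carbon_steel,0.010,170.6,iron curve
carbon_steel,0.015,57.08,iron curve
carbon_steel,0.020,25.68,iron curve
carbon_steel,0.030,8.176,iron curve
carbon_steel,0.040,3.629,iron curve
carbon_steel,0.050,1.958,iron curve
carbon_steel,0.060,1.205,iron curve
carbon_steel,0.080,0.5952,iron curve
carbon_steel,0.100,0.3717,iron curve
carbon_steel,0.150,0.1964,iron curve
carbon_steel,0.200,0.1460,iron curve
carbon_steel,0.300,0.1099,iron curve
carbon_steel,0.400,0.09400,iron curve
carbon_steel,0.500,0.08414,iron curve
carbon_steel,0.600,0.07704,iron curve
carbon_steel,0.800,0.06699,iron curve
carbon_steel,1.000,0.05995,iron curve
carbon_steel,1.250,0.05350,iron curve
carbon_steel,1.500,0.04883,iron curve
carbon_steel,2.000,0.04265,iron curve
carbon_steel,3.000,0.03621,iron curve
stainless_steel,0.010,170.6,iron curve
stainless_steel,0.015,57.08,iron curve
stainless_steel,0.020,25.68,iron curve
stainless_steel,0.030,8.176,iron curve
stainless_steel,0.040,3.629,iron curve
stainless_steel,0.050,1.958,iron curve
stainless_steel,0.060,1.205,iron curve
stainless_steel,0.080,0.5952,iron curve
stainless_steel,0.100,0.3717,iron curve
stainless_steel,0.150,0.1964,iron curve
stainless_steel,0.200,0.1460,iron curve
stainless_steel,0.300,0.1099,iron curve
stainless_steel,0.400,0.09400,iron curve
stainless_steel,0.500,0.08414,iron curve
stainless_steel,0.600,0.07704,iron curve
stainless_steel,0.800,0.06699,iron curve
stainless_steel,1.000,0.05995,iron curve
stainless_steel,1.250,0.05350,iron curve
stainless_steel,1.500,0.04883,iron curve
stainless_steel,2.000,0.04265,iron curve
stainless_steel,3.000,0.03621,iron curve
concrete,0.010,26.23,XCOM-style compilation
concrete,0.015,8.510,XCOM-style compilation
concrete,0.020,3.441,XCOM-style compilation
concrete,0.030,1.308,XCOM-style compilation
concrete,0.040,0.6655,XCOM-style compilation
concrete,0.050,0.4242,XCOM-style compilation
concrete,0.060,0.3199,XCOM-style compilation
concrete,0.080,0.2226,XCOM-style compilation
concrete,0.100,0.1857,XCOM-style compilation
concrete,0.150,0.1480,XCOM-style compilation
concrete,0.200,0.1308,XCOM-style compilation
concrete,0.300,0.1119,XCOM-style compilation
concrete,0.400,0.09951,XCOM-style compilation
concrete,0.500,0.09077,XCOM-style compilation
concrete,0.600,0.08383,XCOM-style compilation
concrete,0.800,0.07360,XCOM-style compilation
concrete,1.000,0.06612,XCOM-style compilation
concrete,1.250,0.05914,XCOM-style compilation
concrete,1.500,0.05380,XCOM-style compilation
concrete,2.000,0.04640,XCOM-style compilation
concrete,3.000,0.03788,XCOM-style compilation
lead,0.100,5.549,XCOM-style compilation above K edge
lead,0.150,2.014,XCOM-style compilation
lead,0.200,0.9985,XCOM-style compilation
lead,0.300,0.4031,XCOM-style compilation
lead,0.400,0.2323,XCOM-style compilation
lead,0.500,0.1614,XCOM-style compilation
lead,0.600,0.1248,XCOM-style compilation
lead,0.800,0.08870,XCOM-style compilation
lead,1.000,0.07102,XCOM-style compilation
lead,1.250,0.05876,XCOM-style compilation
lead,1.500,0.05222,XCOM-style compilation
lead,2.000,0.04606,XCOM-style compilation
lead,3.000,0.04234,XCOM-style compilation
vacuum,0.010,1e-20,numerical vacuum
vacuum,3.000,1e-20,numerical vacuum
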