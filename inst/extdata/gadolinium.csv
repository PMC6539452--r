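# mass attenuation coefficients, elemental Gd, K edge 50.2396 keV, photoelectric E^-3 model anchored at the edge
# density_g_per_cm3: 7.9
energy_keV,mu_over_rho_cm2_per_g,photoelectric_cm2_per_g
20,25.0454,24.6054
30,7.6505,7.2905
40,3.3757,3.0757
50,1.8197,1.5747
50.2,1.8,1.556
50.3,8.013,7.77
60,4.788,4.578
80,2.1113,1.9313
100,1.1488,0.9888
150,0.42,0.293
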