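# mass attenuation coefficients, copper (beam filter), NIST standard grid 20-150 keV
# density_g_per_cm3: 8.96
energy_keV,mu_over_rho_cm2_per_g,photoelectric_cm2_per_g
20,33.79,NA
30,10.92,NA
40,4.862,NA
50,2.613,NA
60,1.593,NA
80,0.763,NA
100,0.4584,NA
150,0.2217,NA
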