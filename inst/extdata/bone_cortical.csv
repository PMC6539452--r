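# mass attenuation coefficients, cortical bone (ICRU-44), NIST standard grid 20-150 keV
# density_g_per_cm3: 1.92
energy_keV,mu_over_rho_cm2_per_g,photoelectric_cm2_per_g
20,4.001,NA
30,1.331,NA
40,0.6655,NA
50,0.4242,NA
60,0.3148,NA
80,0.2229,NA
100,0.1855,NA
150,0.148,NA
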