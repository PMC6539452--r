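# mass attenuation coefficients, polymethyl methacrylate, NIST standard grid 20-150 keV
# density_g_per_cm3: 1.19
energy_keV,mu_over_rho_cm2_per_g,photoelectric_cm2_per_g
20,0.5714,NA
30,0.3032,NA
40,0.235,NA
50,0.2074,NA
60,0.1924,NA
80,0.1751,NA
100,0.1641,NA
150,0.1456,NA
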