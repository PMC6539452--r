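# mass attenuation coefficients, liquid water, NIST standard grid 20-150 keV
# density_g_per_cm3: 1.0
energy_keV,mu_over_rho_cm2_per_g,photoelectric_cm2_per_g
20,0.8096,0.5437
30,0.3756,0.152
40,0.2683,0.0603
50,0.2269,0.0298
60,0.2059,0.0164
80,0.1837,0.00638
100,0.1707,0.00306
150,0.1505,0.000845
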