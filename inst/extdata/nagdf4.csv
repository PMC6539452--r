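# mass attenuation coefficients, NaGdF4 (Gd mass fraction 0.6113), stoichiometric mixture of the Gd table and a water-like light-element complement
# density_g_per_cm3: 4.3
energy_keV,mu_over_rho_cm2_per_g,photoelectric_cm2_per_g
20,15.6091,15.0412
30,4.8154,4.4567
40,2.1626,1.8802
50,1.1962,0.9626
50.2,1.1839,0.9512
50.3,4.9818,4.7498
60,3.0029,2.7985
80,1.3585,1.1806
100,0.7653,0.6045
150,0.3123,0.1791
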