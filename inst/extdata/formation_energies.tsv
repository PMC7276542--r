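name	phase	composition	charge	dGf0	dHf0
H2O	aqueous	H2O	0	-237.18	-285.83
H+	aqueous	H	1	0	NA
OH-	aqueous	HO	-1	-157.24	-229.99
lactate	aqueous	C3H5O3	-1	-515.03	-686.64
lactic_acid	aqueous	C3H6O3	0	-537.06	NA
acetate	aqueous	C2H3O2	-1	-370.43	-486.01
acetic_acid	aqueous	C2H4O2	0	-397.60	NA
pyruvate	aqueous	C3H3O3	-1	-474.63	NA
HCO3	aqueous	CHO3	-1	-587.44	-691.99
CO2(aq)	aqueous	CO2	0	-386.51	NA
CO3	aqueous	CO3	-2	-528.48	NA
SO4	aqueous	SO4	-2	-745.08	-909.27
H2S(aq)	aqueous	H2S	0	-27.28	-38.60
HS	aqueous	HS	-1	12.96	NA
NH4	aqueous	NH4	1	-79.36	-132.51
NH3(aq)	aqueous	NH3	0	-26.56	NA
H2(aq)	aqueous	H2	0	18.87	-4.20
CH4(aq)	aqueous	CH4	0	-34.60	-89.04
biomass	aqueous	C1H1.8O0.5N0.2	0	-67.00	NA
Na	aqueous	Na	1	-261.91	-240.12
Cl	aqueous	Cl	-1	-131.26	-167.16
H2(g)	gas	H2	0	0	0
CO2(g)	gas	CO2	0	-394.36	-393.51
CH4(g)	gas	CH4	0	-50.72	-74.81
H2S(g)	gas	H2S	0	-33.44	-20.63
N2(g)	gas	N2	0	0	0
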