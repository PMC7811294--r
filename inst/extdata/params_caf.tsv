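parameter	value	ci_low	ci_high	unit	role
k1	4.13e-7	4.03e-7	4.21e-7	1/(cell.h)	conversion rate of Gln to NH4+
c1	0.9	0.85	0.92	dimensionless	efficacy of NH4+ production
k2	4.5e-8	4.06e-8	4.89e-8	1/(cell.mM.h)	conversion rate of NH4+ to Gln
c2	0.28	0.28	0.29	dimensionless	efficacy of Gln production
h	1.6e-8	1.33e-8	1.89e-8	mM/(cell.h)	natural production rate of NH4+
k3	2.1e-7	1.83e-7	2.3e-7	1/(cell.h)	consumption rate of alternative energy
r1	2.5e-2	2.39e-2	2.60e-2	1/h	maximal growth rate on Gln
K1	0.63	0.53	0.72	mM	half-maximal Gln concentration
r2	3.45e-6	3.05e-6	3.84e-6	1/h	maximal growth rate on alternative energy
K2	7.3	6.1	8.5	mM	half-maximal alternative energy concentration
d1	1.3e-3	1.27e-3	1.34e-3	1/(mM.h)	NH4+ induced cell death rate
d2	7e-5	6.33e-5	7.67e-5	1/h	background cell death rate
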