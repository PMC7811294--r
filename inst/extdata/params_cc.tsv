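parameter	value	ci_low	ci_high	unit	role
k1	7.5e-8	7.21e-8	7.89e-8	1/(cell.h)	conversion rate of Gln to NH4+
c1	1.9	1.67	2.18	dimensionless	efficacy of NH4+ production
k2	2.4e-8	2.35e-8	2.41e-8	1/(cell.mM.h)	conversion rate of NH4+ to Gln
c2	0.15	0.14	0.16	dimensionless	efficacy of Gln production
h	5.3e-7	5.1e-7	5.6e-7	mM/(cell.h)	natural production rate of NH4+
k3	2.6e-10	1.92e-10	3.37e-10	1/(cell.h)	consumption rate of alternative energy
r1	5.6e-2	5.4e-2	5.8e-2	1/h	maximal growth rate on Gln
K1	1.97	1.93	2.00	mM	half-maximal Gln concentration
d1	1.7e-3	1.6e-3	1.75e-3	1/(mM.h)	NH4+-induced cell death rate
d2	1.1e-2	9.4e-3	1.3e-2	1/h	background cell death rate
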