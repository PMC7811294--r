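parameter	value	ratio	ci_low	ci_high	unit
caf.r1	5e-3	0.1	4.6e-3	5.4e-3	1/h
cc.r1	6e-2	1.08	5.95e-2	6.03e-2	1/h
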