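parameter	value	unit
g	7e-7	1/(h.cell^2)
m	1e-11	1/h
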