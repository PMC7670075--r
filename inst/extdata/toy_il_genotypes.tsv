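marker	chrom	pos_bp	IL01	IL02	IL03
Im1	I	1e+06	A	A	A
Im2	I	3e+06	B	A	A
Im3	I	5e+06	B	A	A
Im4	I	7e+06	B	B	A
Im5	I	9e+06	A	B	A
Im6	I	1.1e+07	A	B	B
Im7	I	1.3e+07	A	A	B
Im8	I	1.5e+07	A	A	B
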