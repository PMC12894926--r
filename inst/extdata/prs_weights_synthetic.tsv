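snp_id	effect_allele	beta
snp01	A	0.04
snp02	C	0.048
snp03	G	0.056
snp04	T	0.064
snp05	A	0.072
snp06	C	0.08
snp07	G	0.088
snp08	T	0.096
snp09	A	0.104
snp10	C	0.112
snp11	G	0.12
snp12	T	0.128
snp13	A	0.136
snp14	C	0.144
snp15	G	0.152
snp16	T	0.16
snp17	A	0.168
snp18	C	0.176
snp19	G	0.184
snp20	T	0.192
snp21	A	0.2
snp22	C	0.208
snp23	G	0.216
snp24	T	0.224
snp25	A	0.232
snp26	C	0.24
snp27	G	0.248
snp28	T	0.256
snp29	A	0.264
snp30	C	0.272
snp31	G	0.28
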