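id	group	species
AtUGT79B2	A	Arabidopsis thaliana
AtUGT89B1	B	Arabidopsis thaliana
AtUGT90A1	C	Arabidopsis thaliana
AtUGT73B3	D	Arabidopsis thaliana
AtUGT71B1	E	Arabidopsis thaliana
AtUGT78D3	F	Arabidopsis thaliana
AtUGT85A1	G	Arabidopsis thaliana
AtUGT76B1	H	Arabidopsis thaliana
AtUGT83A1	I	Arabidopsis thaliana
AtUGT87A1	J	Arabidopsis thaliana
AtUGT86A1	K	Arabidopsis thaliana
AtUGT75C1	L	Arabidopsis thaliana
AtUGT92A1	M	Arabidopsis thaliana
AtUGT82A1	N	Arabidopsis thaliana
AtUGT73C6	D	Arabidopsis thaliana
AtUGT78D1	F	Arabidopsis thaliana
AtUGT76C2	H	Arabidopsis thaliana
GRMZM2G075387	O	Zea mays
GRMZM5G834303	P	Zea mays
GRMZM2G067424	Q	Zea mays
Os02g0755500	G	Oryza sativa
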