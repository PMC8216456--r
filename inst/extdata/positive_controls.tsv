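category	count	members
H/ACA box snoRNA	29	all annotated single-copy H/ACA box snoRNA genes
rRNA	2	5S; 5.8S
tRNA	39	one per anticodon
spliceosomal snRNA	5	U1; U2; U4; U5; U6
U3	1	U3
Telomerase RNA	1	TLC1
RNase MRP	1	NME1
RNase P	1	RPR1
SRP RNA	1	SCR1
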