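set_id	name	layer	k	n	K	N
GO:0008152	metabolic process	mRNA	438	899	6938	34273
GO:0009058	biosynthetic process	mRNA	207	899	3429	34273
GO:0009056	catabolic process	mRNA	63	899	839	34273
GO:0005975	carbohydrate metabolic process	mRNA	36	899	456	34273
GO:0006006	glucose metabolic process	mRNA	18	899	161	34273
GO:0006629	lipid metabolic process	mRNA	79	899	742	34273
GO:0008610	lipid biosynthetic process	mRNA	48	899	324	34273
GO:0019538	protein metabolic process	mRNA	162	899	2325	34273
GO:0006412	ribosome translation	mRNA	53	899	347	34273
GO:0006519	cellular amino acid and derivative metabolic process	mRNA	36	438	312	34273
GO:0006508	proteolysis	mRNA	39	899	567	34273
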