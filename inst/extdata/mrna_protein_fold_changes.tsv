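gene_symbol	fc_mrna	fc_protein
Gbe1	2.3	1.5
Fbp1	-1.9	-1.4
Fh1	-1.6	-1.2
Agxt	-1.8	-1.2
Cth	-1.5	-1.4
Got1	-2.8	-2.1
Gpt	-1.6	-1.3
Oat	-5.0	-2.3
Hgd	-1.7	-1.4
Haao	-2.4	-1.4
Ftcd	-1.6	-1.3
Lap3	-1.4	-1.2
Pah	-1.2	-1.5
Ass1	-1.5	-1.6
Fasn	2.4	1.7
Me1	2.6	1.6
Idi1	2.4	1.7
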