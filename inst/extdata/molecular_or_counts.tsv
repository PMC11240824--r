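outcome	compartment	n_low_yes	n_high_yes	n_low_no	n_high_no	or_printed
clonal	original	113	77	59	62	1.54
clonal	stromal	110	80	56	65	1.60
clonal	epithelial	107	83	66	55	1.07
clonal	tcga	96	426	86	307	0.80
tp53	original	78	44	105	117	1.98
tp53	stromal	74	48	105	117	1.72
tp53	epithelial	71	51	113	109	1.34
tp53	tcga	64	222	118	511	1.25
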