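contrast	variable	index_level	referent_level	n_het_index	n_het_referent	n_hom_index	n_hom_referent	rfd_printed
age_under50	age_group	<50	>=50	314	415	450	476	5.52
race_black	race	Black	non-Black	313	416	491	435	10.09
ror_high	ror	high	low	64	112	167	99	26.42
ror_medium	ror	medium	low	294	112	410	99	8.14
pam50_other	pam50	other	LumA	194	282	359	327	11.58
pam50_basal	pam50	Basal	other	90	386	179	507	7.19
er_negative	er	negative	positive	143	562	250	610	8.79
immune_high	immune_class	high	low	101	307	229	357	14.32
recurrence	recurrence	yes	no	55	471	116	650	4.69
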