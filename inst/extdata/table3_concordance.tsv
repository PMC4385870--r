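patient_id	assay_a	assay_a_abundance_pct	assay_b
SUCRC12	G12D	41	G12D
SUCRC14	G13D	0.04	WT
SUCRC16	G12D	6.5	G12D
SUCRC21	G12V	4.75	G12V
P004	G12S	24	G12S
P008	G12D	17	G12D
A007	G12D	36	G12D
SUCRC24	G13D	1.7	G13D
SUCRC17	WT		WT
SUCRC26	WT		WT
SUCRC27	WT		WT
SUCRC18	G13D	3.8	G13D
SUCRC13	G12D	18	G12D
SUCRC20	G12D	0.285	G12D
P001	WT		WT
SUCRC15	WT		WT
SUCRC19	WT		WT
SUCRC22	WT		Not analyzed
SUCRC23	WT		WT
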