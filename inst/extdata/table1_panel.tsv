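# coordinates are 0-based half-open; alt_allele '-' denotes a deletion
mutation_id	gene	amplicon_id	offset	ref_allele	alt_allele	published_lod_pct
BRAF V600D	BRAF	BRAF_600	61	TG	AT	0.001
BRAF V600E (1799T>A)	BRAF	BRAF_600	61	T	A	0.002
BRAF V600E (1799_1800TG>AA)	BRAF	BRAF_600	61	TG	AA	0.001
BRAF V600K	BRAF	BRAF_600	60	GT	AA	0.001
EGFR E746_A750del_2235	EGFR	EGFR_ex19	62	GGAATTAAGAGAAGC	-	0.001
EGFR E746_A750del_2236	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCA	-	0.001
EGFR E746_A750>IP	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCA	ATTCCA	0.001
EGFR E746_P753>VS	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACATCTCCG	GTTTCC	0.001
EGFR E746_S752>A	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACATCT	GCA	0.001
EGFR E746_S752>D	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACATCT	GAC	0.001
EGFR E746_S752>I	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACATCT	ATC	0.001
EGFR E746_S752>V	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACATCT	GTA	0.001
EGFR E746_T751>A	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACA	GCT	0.001
EGFR E746_T751>I	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACA	ATA	0.001
EGFR E746_T751>IP	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACA	ATTCCT	0.001
EGFR E746_T751>V	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACA	GTG	0.001
EGFR E746_T751>VA	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACA	GTTGCT	0.001
EGFR E746_T751del	EGFR	EGFR_ex19	63	GAATTAAGAGAAGCAACA	-	0.001
EGFR K745_E749del	EGFR	EGFR_ex19	60	AAGGAATTAAGAGAA	-	0.001
EGFR L747_A750>P_2238	EGFR	EGFR_ex19	65	ATTAAGAGAAG	GC	0.001
EGFR L747_A750>P_2239	EGFR	EGFR_ex19	66	TTAAGAGAAGCA	CCT	0.001
EGFR L747_E749del	EGFR	EGFR_ex19	66	TTAAGAGAA	-	0.001
EGFR L747_P753>Q	EGFR	EGFR_ex19	66	TTAAGAGAAGCAACATCTCCG	CAA	0.001
EGFR L747_P753>S	EGFR	EGFR_ex19	66	TTAAGAGAAGCAACATCTCCG	TCA	0.001
EGFR L747_S752>Q	EGFR	EGFR_ex19	66	TTAAGAGAAGCAACATCT	CAG	0.001
EGFR L747_S752del	EGFR	EGFR_ex19	66	TTAAGAGAAGCAACATCT	-	0.001
EGFR L747_T751>P	EGFR	EGFR_ex19	66	TTAAGAGAAGCAACA	CCG	0.001
EGFR L747_T751>Q	EGFR	EGFR_ex19	66	TTAAGAGAAGCAACA	CAA	0.001
EGFR L747_T751>S	EGFR	EGFR_ex19	66	TTAAGAGAAGCAACA	AGT	0.001
EGFR L747_T751del	EGFR	EGFR_ex19	66	TTAAGAGAAGCAACA	-	0.001
EGFR T790M	EGFR	EGFR_790	60	C	T	0.02
EGFR L858R (2573T>G)	EGFR	EGFR_858	60	T	G	0.001
EGFR L858R (2573_2574TG>GT)	EGFR	EGFR_858	60	TG	GT	0.001
KRAS G12A	KRAS	KRAS_12_13	61	G	C	0.003
KRAS G12C	KRAS	KRAS_12_13	60	G	T	0.001
KRAS G12D	KRAS	KRAS_12_13	61	G	A	0.02
KRAS G12R	KRAS	KRAS_12_13	60	G	C	0.001
KRAS G12S	KRAS	KRAS_12_13	60	G	A	0.018
KRAS G12V	KRAS	KRAS_12_13	61	G	T	0.001
KRAS G13C	KRAS	KRAS_12_13	63	G	T	0.008
KRAS G13D	KRAS	KRAS_12_13	64	G	A	0.018
PIK3CA E542K	PIK3CA	PIK3CA_542_546	60	G	A	0.023
PIK3CA E545K	PIK3CA	PIK3CA_542_546	69	G	A	0.024
PIK3CA Q546K	PIK3CA	PIK3CA_542_546	72	C	A	0.007
PIK3CA H1047L	PIK3CA	PIK3CA_1047	60	A	T	0.001
PIK3CA H1047R	PIK3CA	PIK3CA_1047	60	A	G	0.002
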