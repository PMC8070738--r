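##gff-version 3
chrVII	example	gene	1000	2500	.	+	.	ID=GENE_A
chrVII	example	gene	2200	3400	.	+	.	ID=GENE_B
chrVII	example	gene	5000	6200	.	-	.	ID=GENE_C
chrXII	example	gene	100	1900	.	+	.	ID=GENE_D
chrXII	example	gene	2500	3700	.	-	.	ID=GENE_E
chrXVI	example	gene	400	2200	.	+	.	ID=GENE_F
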