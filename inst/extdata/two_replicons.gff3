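##gff-version 3
##sequence-region chr1 1 20000
##sequence-region plas1 1 8000
chr1	sim	CDS	101	1000	.	+	0	ID=cds1;locus_tag=AB_0001;t6ss_component=TssB
chr1	sim	CDS	1201	2100	.	-	0	ID=cds2;locus_tag=AB_0002;t6ss_component=TssC
chr1	sim	CDS	2301	3200	.	+	0	ID=cds3;locus_tag=AB_0003
chr1	sim	gene	101	1000	.	+	.	ID=gene1
chr1	sim	CDS	3401	4300	.	+	0	ID=cds4;locus_tag=AB_0004;t6ss_component=TssN
plas1	sim	CDS	501	1400	.	+	0	ID=cds5;locus_tag=AB_1001;t6ss_component=TssD
plas1	sim	CDS	1601	2500	.	-	0	ID=cds6;locus_tag=AB_1002
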