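##gff-version 3
chr1	example	gene	1001	9000	.	+	.	ID=GENE1
chr1	example	mRNA	1001	9000	.	+	.	ID=GENE1.t1;Parent=GENE1
chr1	example	exon	1001	1243	.	+	.	ID=GENE1.t1.exon1;Parent=GENE1.t1
chr1	example	exon	4001	4143	.	+	.	ID=GENE1.t1.exon2;Parent=GENE1.t1
chr1	example	exon	8001	9000	.	+	.	ID=GENE1.t1.exon3;Parent=GENE1.t1
chr1	example	mRNA	1001	9000	.	+	.	ID=GENE1.t2;Parent=GENE1
chr1	example	exon	1001	1243	.	+	.	ID=GENE1.t2.exon1;Parent=GENE1.t2
chr1	example	exon	8001	9000	.	+	.	ID=GENE1.t2.exon2;Parent=GENE1.t2
chr1	example	gene	20001	26000	.	-	.	ID=GENE2
chr1	example	mRNA	20001	26000	.	-	.	ID=GENE2.t1;Parent=GENE2
chr1	example	exon	20001	20265	.	-	.	ID=GENE2.t1.exon1;Parent=GENE2.t1
chr1	example	exon	23001	23111	.	-	.	ID=GENE2.t1.exon2;Parent=GENE2.t1
chr1	example	exon	25001	26000	.	-	.	ID=GENE2.t1.exon3;Parent=GENE2.t1
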