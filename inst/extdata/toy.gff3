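##gff-version 3
chr1	toy	gene	101	1000	.	+	.	ID=geneA;biotype=protein_coding
chr1	toy	mRNA	101	950	.	+	.	ID=geneA.1;Parent=geneA
chr1	toy	exon	101	950	.	+	.	ID=geneA.1.e1;Parent=geneA.1
chr1	toy	mRNA	101	1000	.	+	.	ID=geneA.2;Parent=geneA
chr1	toy	exon	101	1000	.	+	.	ID=geneA.2.e1;Parent=geneA.2
chr1	toy	gene	2001	2800	.	-	.	ID=geneB;biotype=protein_coding
chr1	toy	mRNA	2001	2800	.	-	.	ID=geneB.1;Parent=geneB
chr1	toy	exon	2001	2800	.	-	.	ID=geneB.1.e1;Parent=geneB.1
chr2	toy	gene	201	900	.	+	.	ID=rrna1;biotype=rRNA
chr2	toy	rRNA	201	900	.	+	.	ID=rrna1.1;Parent=rrna1
chr2	toy	exon	201	900	.	+	.	ID=rrna1.1.e1;Parent=rrna1.1
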