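##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	demi_1	demi_2	demi_3	demi_4	black_1	black_2	black_3	black_4
scaf1	1000000	.	A	G	94.3	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/1	1/1	0/0
scaf1	2000000	.	A	G	100.4	PASS	.	GT	0/0	0/0	0/0	0/1	0/1	0/1	0/0	0/1
scaf1	3000000	.	A	G	71.1	PASS	.	GT	0/0	0/0	0/1	1/1	0/0	0/1	0/1	0/1
scaf1	4000000	.	A	G	160.6	PASS	.	GT	0/1	1/1	0/1	0/1	0/1	0/0	0/0	0/0
scaf1	5000000	.	A	G	149.1	PASS	.	GT	1/1	0/0	0/0	0/0	0/1	0/1	0/1	1/1
scaf1	6000000	.	A	G	96.3	PASS	.	GT	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0
scaf1	7000000	.	A	G	188.7	PASS	.	GT	0/1	0/0	0/0	1/1	0/0	0/0	0/0	0/0
scaf1	8000000	.	A	G	46.9	PASS	.	GT	0/0	0/0	0/0	0/0	1/1	0/0	0/0	0/1
scaf1	9000000	.	A	G	84.9	PASS	.	GT	1/1	0/0	0/1	0/0	0/0	0/1	0/1	0/1
scaf1	10000000	.	A	G	164.7	PASS	.	GT	0/1	0/0	0/1	1/1	1/1	0/0	0/0	1/1
scaf1	11000000	.	A	G	111.3	PASS	.	GT	0/0	0/1	0/1	0/0	0/1	0/0	0/1	0/1
scaf1	12000000	.	A	G	66.5	PASS	.	GT	1/1	1/1	1/1	1/1	0/0	0/1	0/0	1/1
scaf1	13000000	.	A	G	46.4	PASS	.	GT	0/0	0/0	0/0	0/1	0/1	0/0	0/0	0/1
scaf1	14000000	.	A	G	98.9	PASS	.	GT	0/0	0/0	0/0	0/0	0/1	0/0	1/1	0/0
scaf1	15000000	.	A	G	87.0	PASS	.	GT	0/0	0/1	0/0	0/1	0/1	1/1	1/1	1/1
scaf2	1000000	.	A	G	154.2	PASS	.	GT	0/1	1/1	0/0	0/1	0/1	0/0	1/1	1/1
scaf2	2000000	.	A	G	121.3	PASS	.	GT	0/0	0/0	0/0	1/1	0/0	0/1	0/0	0/0
scaf2	3000000	.	A	G	190.4	PASS	.	GT	0/1	0/1	0/0	0/0	0/1	0/1	0/0	0/0
scaf2	4000000	.	A	G	76.8	PASS	.	GT	0/0	0/1	0/0	0/0	0/0	1/1	0/0	1/1
scaf2	5000000	.	A	G	191.5	PASS	.	GT	0/0	0/0	0/0	0/0	1/1	0/0	0/0	0/0
scaf2	6000000	.	A	G	187.4	PASS	.	GT	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0
scaf2	7000000	.	A	G	182.2	PASS	.	GT	0/0	0/0	0/1	0/0	0/0	0/0	0/1	0/1
scaf2	8000000	.	A	G	151.4	PASS	.	GT	0/1	0/1	0/1	0/1	0/1	0/0	0/0	0/1
scaf2	9000000	.	A	G	40.7	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0
scaf2	10000000	.	A	G	177.9	PASS	.	GT	0/1	0/0	0/0	0/0	0/1	0/0	0/0	0/0
scaf2	11000000	.	A	G	58.0	PASS	.	GT	0/1	0/0	0/1	0/0	0/1	0/1	0/1	0/0
scaf2	12000000	.	A	G	85.9	PASS	.	GT	0/1	0/1	0/1	1/1	0/0	1/1	0/1	1/1
scaf2	13000000	.	A	G	159.2	PASS	.	GT	0/0	0/1	0/1	0/0	0/0	0/1	0/0	1/1
scaf2	14000000	.	A	G	52.1	PASS	.	GT	0/1	0/0	0/0	0/1	0/1	1/1	0/0	1/1
scaf2	15000000	.	A	G	145.4	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0	1/1	1/1
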