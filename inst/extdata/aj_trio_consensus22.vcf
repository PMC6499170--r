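##fileformat=VCFv4.2
##source=trioDNSNV fixture: the 22 de novo SNVs called concordantly by GATK, RTG and VarScan on the GIAB Ashkenazi Jewish trio exomes (chrom, pos, substitution and gene as printed; per-sample GT/AD/GQ fields are synthetic placeholders; record order follows the printed listing)
##INFO=<ID=GENE,Number=1,Type=String,Description="Gene symbol where reported">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	FATHER	MOTHER	CHILD
2	25457155	.	C	T	.	.	GENE=DTNB	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
2	197791183	.	C	T	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
2	241835203	.	G	T	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
3	4669342	.	A	T	.	.	GENE=ITPR1	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
3	48603870	.	G	A	.	.	GENE=UQCRC1	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
3	52547912	.	C	G	.	.	GENE=PBRM1	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
6	109740508	.	T	C	.	.	GENE=FIG4	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
5	140730969	.	A	G	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
8	30703949	.	C	G	.	.	GENE=GSR	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
9	131041047	.	G	T	.	.	GENE=LAMC3	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
9	131851319	.	C	G	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
11	82698724	.	T	C	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
14	77245340	.	C	T	.	.	GENE=TMEM63C	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
14	93170535	.	G	A	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
14	96180196	.	C	G	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
14	106330036	.	T	A	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
14	106993919	.	A	G	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
15	79852462	.	G	T	.	.	GENE=MTHFS	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
17	53638886	.	G	A	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
19	45720935	.	C	T	.	.	GENE=FBXO46	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
22	23029544	.	A	C	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
22	23029596	.	A	T	.	.	.	GT:AD:GQ	0/0:30,0:99	0/0:30,0:99	0/1:15,15:99
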