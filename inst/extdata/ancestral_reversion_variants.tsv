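chrom	pos	ref	alt	gene	hgvs	clinvar	hgmd_class	ancestral_allele	ancestral_confidence	orth_1to1	orth_1tomany
chr1	1000	A	G	ABCA4	NM_000350.2:c.1268A>G	Benign;Likely benign	DM	G	high	112	15
chr1	2000	G	A	ABCC6	NM_001171.5:c.3961G>A	Pathogenic	none	A	high	88	3
chr1	3000	T	C	ABCC6	NM_001171.5:c.1233T>C	Likely benign	DM	C	high	88	3
chr1	4000	T	C	ANK1	NM_000037.3:c.-108T>C	Pathogenic	DM?	C	high	81	45
chr1	5000	C	G	ARSA	NM_000487.5:c.1178C>G	Benign;Pathogenic	DP	G	high	117	11
chr1	6000	T	C	ASPM	NM_018136.4:c.7787T>C	Benign	DM	C	high	123	5
chr1	7000	G	A	BCL11A	NM_018014.3:c.386-24278G>A	Likely pathogenic	none	A	high	127	2
chr1	8000	C	T	CBS	NM_000071.2:c.992C>T	Pathogenic	none	T	high	0	88
chr1	9000	G	A	CLCN7	NM_001287.5:c.1252G>A	Benign	DM	A	high	130	1
chr1	10000	G	A	COL4A4	NM_000092.4:c.3979G>A	Likely pathogenic	none	A	high	86	12
chr1	11000	C	T	CRYAB	NM_001885.2:c.166C>T	Pathogenic	none	T	high	118	8
chr1	12000	T	C	DHCR7	NM_001360.2:c.438T>C	Benign	DM	C	high	125	4
chr1	13000	T	C	DPYD	NM_000110.3:c.85T>C	Pathogenic	DFP	C	high	126	6
chr1	14000	G	A	DRAM2	NM_178454.4:c.131G>A	Pathogenic	none	A	high	116	13
chr1	15000	T	C	EYA1	NM_000503.5:c.1755T>C	Benign	DM	C	high	130	2
chr1	16000	G	A	FBN1	NM_000138.4:c.2180G>A	Pathogenic	none	A	high	113	12
chr1	17000	T	C	FGFR1	NM_023110.2:c.899T>C	Pathogenic	none	C	high	88	43
chr1	18000	A	G	GJB2	NM_004004.5:c.487A>G	Likely benign;Pathogenic	none	G	high	69	14
chr1	19000	C	T	HEPACAM	NM_152722.4:c.274C>T	Pathogenic	none	T	high	81	48
chr1	20000	T	C	KEL	NM_000420.2:c.1790T>C	Pathogenic	FP	C	high	68	2
chr1	21000	T	C	KRT14	NM_000526.4:c.369T>C	.	DM	C	high	61	0
chr1	22000	G	A	MAK	NM_001242957.1:c.37G>A	Pathogenic	none	A	high	110	21
chr1	23000	C	G	MYH7	NM_000257.3:c.5507C>G	Pathogenic	none	G	high	109	9
chr1	24000	C	T	NPHS1	NM_004646.3:c.1219C>T	Likely pathogenic	none	T	high	121	3
chr1	25000	G	C	OTOF	NM_194248.2:c.2736G>C	Benign	DM	C	high	127	3
chr1	26000	C	G	RAF1	NM_002880.3:c.781C>G	Pathogenic	none	G	high	112	16
chr1	27000	G	A	RARS2	NM_020320.3:c.953G>A	Likely pathogenic	none	A	high	132	0
chr1	28000	A	G	SCN5A	NM_198056.2:c.1673A>G	Benign;Pathogenic	DFP	G	high	68	2
chr1	29000	G	A	SLC17A5	NM_012434.4:c.983G>A	Likely pathogenic	none	A	high	81	2
chr1	30000	C	G	SLC45A2	NM_016180.4:c.1122C>G	Association;Protective	DM	G	high	131	2
chr1	31000	A	G	SLC45A2	NM_016180.4:c.987A>G	Benign	DM	G	high	131	2
chr1	32000	C	T	SPG11	NM_025137.3:c.7023C>T	Benign	DM	T	high	125	7
chr1	33000	A	G	STAT1	NM_007315.3:c.494A>G	Pathogenic	none	G	high	117	14
chr1	34000	T	G	TAS2R16	NM_016945.2:c.516T>G	Pathogenic;risk factor	DFP	G	high	25	1
chr1	35000	A	G	XDH	NM_000379.3:c.3276+12A>G	Likely pathogenic	none	G	high	128	6
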