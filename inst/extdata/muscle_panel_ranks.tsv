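gene	RF	ELNET	SVM_PFI	SVM_log2FC=3	SVM_log2FC=-3	DFS	DE	final_rank
SKAP2	1	1	22	6	7	44	10	1
FAM171A1	5	5	25	14	52	180	5	2
PLAG1	2	2	159	55	106	1	6	3
PCDH9	242	204	110	19	27	38	23	4
KBTBD11	19	20	112	70	455	34	31	5
GREM1	3	3	109	441	229	6	11	6
GREB1	41	52	16	72	86	28	653	7
VSNL1	324	332	5	1	1	7	297	8
TES	140	238	49	54	8	507	140	9
SLC38A1	8	9	63	28	1048	14	9	10
OSBPL3	133	144	31	48	233	19	774	11
PPEF1	384	369	67	67	39	9	619	12
EPB41L3	15	14	194	179	1324	15	4	13
CLEC2B	11	11	681	844	165	463	19	14
CDKN1A	192	191	638	548	447	75	123	15
CA4	222	261	98	428	598	317	308	16
HPGDS	321	399	418	795	188	41	97	17
ACSL6	506	380	84	288	118	263	705	18
LGI1	73	90	219	1864	305	82	22	19
KCNN3	249	212	158	906	452	485	291	20
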