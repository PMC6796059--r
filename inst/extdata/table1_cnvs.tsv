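cell	chrom	start_mb	end_mb	size_mb	direction	cnv_class	start_terminal	end_terminal	site_start	site_end
1	chr5	0	26	26	gain	segmental	TRUE	FALSE	.	FRA5E
1	chr12	0	48	48	gain	segmental	TRUE	FALSE	.	FRA12A
1	chr6	0	29	29	gain	segmental	TRUE	FALSE	.	FRA6E
1	chr20	0	11.5	11.5	loss	segmental	TRUE	FALSE	.	FRA20B
2	chr1	33	46.5	13.5	gain	segmental	FALSE	FALSE	.	.
2	chrX	57.5	81.5	24	gain	segmental	FALSE	FALSE	.	.
2	chr3	60.5	69.5	9	gain	segmental	FALSE	FALSE	FRA3B	.
3	chr3	60.5	69.5	9	gain	segmental	FALSE	FALSE	FRA3B	.
4	chr3	60.5	69.5	9	gain	segmental	FALSE	FALSE	FRA3B	.
4	chr11	68	82	14	gain	segmental	FALSE	FALSE	.	FRA11EH
5	chr3	60.5	69.5	9	gain	segmental	FALSE	FALSE	FRA3B	.
5	chr4	119.5	129.5	10	gain	segmental	FALSE	FALSE	.	.
5	chr13	50	59	9	gain	segmental	FALSE	FALSE	.	FRA13b
6	chr1	35.5	150.5	115	gain	segmental	FALSE	FALSE	.	FRA1F
6	chr2	158.5	242	84	gain	segmental	FALSE	TRUE	.	.
6	chr4	0	54.5	54.5	gain	segmental	TRUE	FALSE	.	FRA4b
6	chr4	118	190	72	loss	segmental	FALSE	TRUE	.	.
6	chr9	95	138.5	43.5	loss	segmental	FALSE	TRUE	.	.
6	chr10	104	134	30	loss	segmental	FALSE	TRUE	FRA10A	.
6	chr14	0	107	107	gain	whole_chromosome	TRUE	TRUE	.	.
6	chr16	0	90	90	gain	whole_chromosome	TRUE	TRUE	.	.
6	chr17	27.5	58.5	31	loss	segmental	FALSE	FALSE	.	FRA17B
7	chr11	68.5	95.5	27	gain	segmental	FALSE	FALSE	FRA11EH	.
8	chr1	30	94	64	gain	segmental	FALSE	FALSE	FRA1D	FRA1M
8	chr12	100	133	33	gain	segmental	FALSE	TRUE	.	.
9	chr3	38.5	120.5	82	loss	segmental	FALSE	FALSE	.	.
9	chr3	149.5	198.5	49	gain	segmental	FALSE	TRUE	FRA3D	.
9	chr5	79	181.5	102.5	loss	segmental	FALSE	TRUE	.	.
9	chr7	69	159.5	90	loss	segmental	FALSE	TRUE	FRA7J	.
9	chr12	106	133.5	27.5	loss	segmental	FALSE	TRUE	.	.
9	chr16	81	90	9	loss	segmental	FALSE	TRUE	FRA16D	.
10	chr3	137.5	198.5	61	loss	segmental	FALSE	TRUE	.	.
10	chr4	105	142	37	gain	segmental	FALSE	FALSE	.	.
10	chr7	16.5	52	35.5	gain	segmental	FALSE	FALSE	.	.
11	chr7	0	87	87	gain	segmental	TRUE	FALSE	.	.
12	chr1	0	249	249	loss	whole_chromosome	TRUE	TRUE	.	.
12	chr21	0	40	40	loss	whole_chromosome	TRUE	TRUE	.	.
12	chr2	98	134.5	36.5	gain	segmental	FALSE	FALSE	FRA2A	FRA2S-2F
12	chr2	164	242	78	loss	segmental	FALSE	TRUE	.	.
12	chr4	0	190	190	loss	whole_chromosome	TRUE	TRUE	.	.
12	chr5	75.5	181.5	106	loss	segmental	FALSE	TRUE	.	.
12	chr7	0	159.5	159.5	loss	whole_chromosome	TRUE	TRUE	.	.
12	chr8	0	39	39	gain	segmental	TRUE	FALSE	.	.
12	chr8	103	145	42	gain	segmental	FALSE	TRUE	FRA8A	.
12	chr10	0	134	134	loss	whole_chromosome	TRUE	TRUE	.	.
12	chr12	0	133	133	gain	whole_chromosome	TRUE	TRUE	.	.
12	chr14	38.5	73	34.5	gain	segmental	FALSE	FALSE	.	.
12	chr18	0	54.5	54.5	gain	segmental	TRUE	FALSE	.	FRA18B
12	chr19	0	58.5	58.5	loss	whole_chromosome	TRUE	TRUE	.	.
13	chr16	31.5	55	23.5	gain	segmental	FALSE	FALSE	.	.
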