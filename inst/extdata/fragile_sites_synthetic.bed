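chr1	29250000	30750000	FRA1D
chr1	93250000	94750000	FRA1M
chr1	149750000	151250000	FRA1F
chr2	97250000	98750000	FRA2A
chr2	133750000	135250000	FRA2S-2F
chr3	59900000	61400000	FRA3B
chr3	148750000	150250000	FRA3D
chr4	53750000	55250000	FRA4b
chr5	25250000	26750000	FRA5E
chr6	28250000	29750000	FRA6E
chr7	68250000	69750000	FRA7J
chr8	102250000	103750000	FRA8A
chr10	103250000	104750000	FRA10A
chr11	68400000	82300000	FRA11EH
chr12	47250000	48750000	FRA12A
chr13	58250000	59750000	FRA13b
chr16	80250000	81750000	FRA16D
chr17	57750000	59250000	FRA17B
chr18	53750000	55250000	FRA18B
chr20	10750000	12250000	FRA20B
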