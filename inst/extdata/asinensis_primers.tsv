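primer_id	locus_id	motif	forward	reverse
AquSSR07	Scaffold_5532_102997041	CA	AAACGGAACGTGCTAATGCT	CCACACGTGATTTCTGGATG
AquSSR10	Scaffold_9996_84841276	ATG	TATTAGTGGGTGAATCGGGC	GGGCAAACGGTATAATCATCA
AquSSR14	Scaffold_15334_39078260	AT	GACATAAGGGGCCATGAGTG	AAGCCTAGCCTTTTTGGTGG
AquSSR17	Scaffold_10796_83936585	AAT	CAAAACCAAATTCACTTGAAAGC	CCACCAGCACAAGTGGTATG
AquSSR18	Scaffold_10796_86795031	ATT	GGAGAGGGTTGAGGTAGGGT	CGGTGTTTGAGATTGTGGAA
AquSSR22	Scaffold_8152_21061737	TG	GGAACTCAATAGGCTGCTGG	CAAATTTTGGGTTGGGTACG
AquSSR27	Scaffold_3585_12180739	TTC	CATTTTACTTTTTGGCGGGA	TGCAACACAAGCAACACAAA
AquSSR28	Scaffold_3585_77017729	AAT	CGAGTGAGGGTTCACCAACT	TGCTCCATAAATGCATGCTC
AquSSR29	Scaffold_10546_3054275	GAA	AACACCTTCATCACCGGAAG	GGGCTTTTGTCATTTTCCCT
AquSSR30	Scaffold_10546_7777087	GA	TTAGCATGGTTTTGTGCTGG	TGCACAACCTCCTCTCTGTG
AquSSR34	Scaffold_10546_70298677	ATAC	ACCATGGACCACAGAGAAGC	AAGGGTATGTGTTGAAGGCG
AquSSR40	Scaffold_10433_55273834	TTA	TCTCCCACGTTTCCAACTTC	TTTGGTCACGAAAAGTGGTG
AquSSR42	Scaffold_10433_59579622	TAT	AACCCTTGTTTGAATGCAGG	CCTAATGGCTGAAAGCCTGA
AquSSR54	Scaffold_10796_47706258	TTA	TGCCCTTTAGACCATGGAAG	AGACCAATAGACCCAAGATGG
AquSSR58	Scaffold_3585_1832452	AAC	CAATGGGGTTTCTACAGGCA	TTGTTGGACATCACAAACGG
AquSSR59	Scaffold_3585_64368533	GCT	AGGGGAGGTGAAGAAAAGGA	CCATAACCATAGCAGCAGCA
AquSSR62	Scaffold_10546_2555776	ATA	TGTGTGGGTAAAATGAAGGCT	TGCCTAAATCTCCTTTGCTTTC
AquSSR71	Scaffold_5532_21554441	AAG	CGCAACCTCATGGGTAACTT	AACCAATCCTCAAACCTCCC
AquSSR89	Scaffold_10546_79030278	TAA	TTTTAATCAGGGGAGGACCC	TCTGCTGACGTGTACGGTTC
AquSSR94	Scaffold_10433_72319168	TAA	CCACTGTTTCTGCAAGCTAGG	GACTTCGTGATCTCAACGGG
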