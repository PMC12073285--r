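source	df	SS	MS	sigma2
among_populations	2	130.156	65.078	0.636
among_individuals	146	804.267	5.509	0.290
within_individuals	149	734.500	4.930	4.930
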