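population	N	Na	Ne	I	Ho	He	F
I	70.750	4.600	2.280	0.934	0.484	0.505	0.050
II	29.750	4.800	2.816	1.141	0.561	0.603	0.063
III	47.950	3.850	2.141	0.851	0.471	0.470	-0.002
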