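class	label	count
mono	A/T	3013
mono	C/G	1734
di	all	41695
tri	all	9550
tetra	all	644
penta	all	13
hexa	all	8
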