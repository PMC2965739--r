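#! biomass Biomass
id	equation	lb	ub	gpr
EX_A	A(e) <=>	-10	1000	
T_A	A(e) -> A(c)	0	1000	
R_AB	A(c) -> B(c)	0	1000	
R_BC	B(c) -> C(c)	0	1000	(G1)
R_AD	A(c) -> D(e)	0	1000	(G2)
EX_D	D(e) ->	0	1000	
Biomass	C(c) ->	0	1000	
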