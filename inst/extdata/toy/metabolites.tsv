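id	compartment
A(c)	c
A(e)	e
B(c)	c
C(c)	c
D(e)	e
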