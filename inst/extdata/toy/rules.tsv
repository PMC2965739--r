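#! tf TF1
#! tf TF2
target	rule
G1	TF1
TF1	NOT A(e)>0
G2	NOT TF2
TF2	ON
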