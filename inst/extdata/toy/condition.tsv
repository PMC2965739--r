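#! id A medium
#! aerobic false
#! o2_uptake 10
metabolite	uptake
A	10
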