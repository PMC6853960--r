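D1	mA
D1	mB
D1	mC
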