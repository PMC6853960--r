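G11	G12
G11	G13
G11	G14
G12	G13
G12	G14
G13	G14
G21	G22
G21	G23
G21	G24
G22	G23
G22	G24
G23	G24
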