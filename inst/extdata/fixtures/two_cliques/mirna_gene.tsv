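m11	G11
m11	G12
m11	G13
m11	G14
m12	G11
m12	G12
m12	G13
m12	G14
m13	G11
m13	G12
m13	G13
m13	G14
m21	G21
m21	G22
m21	G23
m21	G24
m22	G21
m22	G22
m22	G23
m22	G24
m23	G21
m23	G22
m23	G23
m23	G24
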