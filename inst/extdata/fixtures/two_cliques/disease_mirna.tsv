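D11	m11
D11	m12
D11	m13
D12	m11
D12	m12
D12	m13
D13	m11
D13	m12
D13	m13
D14	m11
D14	m12
D14	m13
D15	m11
D15	m12
D15	m13
D21	m21
D21	m22
D21	m23
D22	m21
D22	m22
D22	m23
D23	m21
D23	m22
D23	m23
D24	m21
D24	m22
D24	m23
D25	m21
D25	m22
D25	m23
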