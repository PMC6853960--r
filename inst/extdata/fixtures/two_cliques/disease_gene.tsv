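D11	G11
D11	G12
D11	G13
D11	G14
D12	G11
D12	G12
D12	G13
D12	G14
D13	G11
D13	G12
D13	G13
D13	G14
D14	G11
D14	G12
D14	G13
D14	G14
D15	G11
D15	G12
D15	G13
D15	G14
D21	G21
D21	G22
D21	G23
D21	G24
D22	G21
D22	G22
D22	G23
D22	G24
D23	G21
D23	G22
D23	G23
D23	G24
D24	G21
D24	G22
D24	G23
D24	G24
D25	G21
D25	G22
D25	G23
D25	G24
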