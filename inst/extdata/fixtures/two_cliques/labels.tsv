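disease_a	disease_b	label
D11	D12	positive
D11	D13	positive
D11	D14	positive
D11	D15	positive
D12	D13	positive
D12	D14	positive
D12	D15	positive
D13	D14	positive
D13	D15	positive
D14	D15	positive
D21	D22	positive
D21	D23	positive
D21	D24	positive
D21	D25	positive
D22	D23	positive
D22	D24	positive
D22	D25	positive
D23	D24	positive
D23	D25	positive
D24	D25	positive
D11	D21	negative
D12	D21	negative
D13	D21	negative
D14	D21	negative
D15	D21	negative
D11	D22	negative
D12	D22	negative
D13	D22	negative
D14	D22	negative
D15	D22	negative
D11	D23	negative
D12	D23	negative
D13	D23	negative
D14	D23	negative
D15	D23	negative
D11	D24	negative
D12	D24	negative
D13	D24	negative
D14	D24	negative
D15	D24	negative
D11	D25	negative
D12	D25	negative
D13	D25	negative
D14	D25	negative
D15	D25	negative
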