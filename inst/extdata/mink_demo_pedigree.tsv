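individual	sire	dam
F1	NA	NA
F2	NA	NA
F3	NA	NA
F4	NA	NA
G1_1_1	F1	F2
G1_1_2	F1	F2
G2_1	G1_1_1	G1_1_2
G1_2_1	F3	F4
G1_2_2	F3	F4
G2_2	G1_2_1	G1_2_2
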