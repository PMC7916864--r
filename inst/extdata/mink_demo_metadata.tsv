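sample	group	supergroup
demi_1	demi	farmA
demi_2	demi	farmA
demi_3	demi	farmA
demi_4	demi	farmA
black_1	black	farmB
black_2	black	farmB
black_3	black	farmB
black_4	black	farmB
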