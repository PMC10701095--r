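a1	U	CattleA	D
a2	U	CattleA	D
b1	U	CattleB	D
b2	U	CattleB	D
o1	U	Out	D
o2	U	Out	D
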