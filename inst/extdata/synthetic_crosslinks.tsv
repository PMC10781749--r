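protein_a	residue_a	protein_b	residue_b	ld_score	delta_s
TssX	1	TssX	5	30	0.5
TssX	1	TssX	5	35	0.4
TssX	2	TssX	12	28	0.99
TssX	1	TssX	19	40	0.3
TssX	1	TssX	25	33	0.2
TssY	3	TssX	8	29	0.1
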