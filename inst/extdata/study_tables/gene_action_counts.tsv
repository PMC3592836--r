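subgroup	below_low	low_parent	mid_parent	high_parent	above_high
HTiU	187	65	1	79	3094
HP1	7	210	407	850	1173
HPco	237	0	0	0	1787
co	16	35	20	0	142
HTaU	289	176	6	13	1114
HP2	6	646	73	100	219
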