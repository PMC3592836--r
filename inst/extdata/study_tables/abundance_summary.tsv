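sample	transcripts_all	transcripts_unique	fpkm_lt1	fpkm_gt100	genes_all	genes_unique	cov_lt0.2	cov_gt0.8
tiger	36760	1676	19444	836	16399	325	7039	3154
tawny	38238	2096	17136	1101	16912	470	5179	5384
hybrid	38178	1953	14910	1427	17032	517	5080	5634
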