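term_id	Up1	Up2	Down1	Down2	fdr
intracellular	215	296	14	63	7.12e-5
nucleotide_binding	76	111	9	21	1.88e-4
gtpase_regulator_activity	17	26	2	7	2.81e-4
ligase_activity	23	15	5	3	2.81e-4
hydrolase_activity	65	110	4	25	5.86e-4
protein_metabolic_process	72	136	5	22	2.10e-3
cellular_catabolic_process	43	41	3	7	2.33e-3
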