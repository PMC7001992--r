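label	events	total	decimals
ftz_four_stripes	30	46	0
no_pole_cells	63	66	0
osk_mrna_posterior_stage9_10a	41	43	0
osk_protein_posterior_stage9_10a	3	43	0
osk_mrna_unanchored_stage10b	30	34	0
osk_protein_posterior_stage10b	2	34	0
hatched_mkrn1w	40	1222	1
hatched_mkrn1w_bru1_het	620	2058	1
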