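phenotype	set_name	size	effect_pct	se_pct	phi_size
PAR-dr	type_1_diabetes	44	13.43	0.69	69
PAR-dr	psmd4_targets	73	9.38	0.53	69
PAR-dr	graft_versus_host_disease	42	14.08	0.70	69
PAR-dr	allograft_rejection	38	15.58	0.75	69
PAR-dr	antigen_processing_presentation	89	6.53	0.49	69
PAR-dr	viral_myocarditis	73	8.01	0.54	69
WL-dr	type_1_diabetes	44	26.74	1.10	173
WL-dr	psmd4_targets	73	18.64	0.85	173
WL-dr	graft_versus_host_disease	42	28.04	1.13	173
WL-dr	allograft_rejection	38	31.04	1.18	173
WL-dr	antigen_processing_presentation	89	12.97	0.77	173
WL-dr	viral_myocarditis	73	15.90	0.85	173
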