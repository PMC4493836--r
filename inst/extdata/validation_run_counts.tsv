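sample	gene	digester	n_paired	n_merged	n_peptides	reported_sensitivity_pct	consistent
mcrA_AD	mcrA	AD	17365	12816	11931	93	TRUE
mcrA_WD	mcrA	WD	9277	4318	2572	59	TRUE
mcrB_AD	mcrB	AD	32094	23188	21939	94	TRUE
mcrB_WD	mcrB	WD	50485	40242	25035	57	FALSE
mcrG_AD	mcrG	AD	42185	29330	21988	74	TRUE
mcrG_WD	mcrG	WD	34945	28660	18272	63	TRUE
mtaB_AD	mtaB	AD	26500	20753	19163	92	TRUE
mtaB_WD	mtaB	WD	36148	15293	13231	86	TRUE
mtbA_AD	mtbA	AD	33770	22852	10027	43	TRUE
mtbA_WD	mtbA	WD	31601	19150	10961	57	TRUE
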