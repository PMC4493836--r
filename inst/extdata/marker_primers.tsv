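name	sequence	orientation	gene	expected_product_bp	max_mismatch
LMCRB	TWYCARGGHYTVAAYGC	forward	mcrB	392	2
RMCRB	CCDCCDCCDCCRTARAT	reverse	mcrB	392	2
LMCRG1	CAYCCDCCDYTNGADGARATGGA	forward	mcrG	356	4
RMCRG1	TCRAACATYANWCCRTYYTCRTC	reverse	mcrG	356	4
LMTAB	CARGCHAAYACYGCMATGTT	forward	mtaB	436	2
RMTAB	CYTGDGGRTCYCKGTA	reverse	mtaB	436	2
LMTBA	TTCTCCCTTGCMCAGCA	forward	mtbA	413	2
RMTBA	ACWGGRTCVAGRTTWCC	reverse	mtbA	413	2
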