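drug_id	target_id	combined_score	sources	n_sources
gc1	ANXA1	0.7	stitch	1
gc1	NR3C1	0.94	batman,stitch	2
gc1	TSC22D3	0.65	batman	1
gc2	DUSP1	1	pubchem,stitch	2
gc2	NR3C1	0.9	stitch	1
gc2	TSC22D3	0.7	batman	1
gc3	ANXA1	0.75	batman,pubchem	2
gc3	IL2	0.62	stitch	1
gc3	NR3C1	0.8	stitch	1
nsaid1	PTGS1	0.95	stitch	1
nsaid1	PTGS2	1	pubchem,stitch	2
nsaid2	ALOX5	0.83	batman,pubchem	2
nsaid2	PTGS2	0.88	stitch	1
nsaid3	CXCL8	0.58	stitch	1
nsaid3	PTGS1	0.72	batman	1
nsaid3	PTGS2	0.8	stitch	1
xypq	CXCL8	0.52	stitch	1
xypq	IL2	0.545	batman,stitch	2
xypq	NR3C1	0.45	batman	1
xypq	PTGS2	0.55	batman	1
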