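drug_id	target_id	source	probability
# glucocorticoid-like reference drugs
gc1	NR3C1	stitch	0.85
gc1	NR3C1	batman	0.6
gc1	ANXA1	stitch	0.7
gc1	TSC22D3	batman	0.65
gc1	PTGS1	batman	0.2
gc2	NR3C1	stitch	0.9
gc2	DUSP1	stitch	0.55
gc2	DUSP1	pubchem	active
gc2	TSC22D3	batman	0.7
gc3	NR3C1	stitch	0.8
gc3	ANXA1	batman	0.5
gc3	ANXA1	pubchem	inconclusive
gc3	IL2	stitch	0.62
# NSAID-like reference drugs
nsaid1	PTGS1	stitch	0.95
nsaid1	PTGS2	stitch	0.9
nsaid1	PTGS2	pubchem	active
nsaid2	PTGS2	stitch	0.88
nsaid2	ALOX5	batman	0.66
nsaid2	ALOX5	pubchem	inconclusive
nsaid2	ANXA1	batman	0.3
nsaid3	PTGS1	batman	0.72
nsaid3	PTGS2	stitch	0.8
nsaid3	CXCL8	stitch	0.58
nsaid3	IL2	pubchem	inactive
# query drug, recorded per composition
comp_a	NR3C1	batman	0.45
comp_a	IL2	stitch	0.3
comp_a	IL2	batman	0.35
comp_b	IL2	stitch	0.5
comp_b	PTGS2	batman	0.55
comp_b	CXCL8	stitch	0.35
comp_c	CXCL8	stitch	0.52
comp_c	PTGS2	batman	0.4
comp_c	NR3C1	batman	0.3
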