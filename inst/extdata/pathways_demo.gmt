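PW_INF1	positive regulation of inflammatory response	PTGS1	PTGS2	ALOX5	CXCL8	IL2
PW_INF2	cytokine production involved in inflammatory response	IL2	CXCL8	CCL4	NFKBIA
PW_IMM1	innate immune response	NR3C1	ANXA1	DUSP1	PTPN6	SRC
PW_IMM2	leukocyte migration	ICAM1	MMP9	CXCL8	PTGS2
PW_GC	cellular response to glucocorticoid stimulus	NR3C1	TSC22D3	DUSP1	ANXA1
PW_MET	xenobiotic metabolic process	CYP1A1	CYP2E1
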