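gene	fc	fdr	contrast
PTGS1	1.9	0.02	xyp_vs_model
PTGS2	2.2	0.01	xyp_vs_model
ALOX5	1.6	0.08	xyp_vs_model
CXCL8	1.5	0.1	xyp_vs_model
IL2	0.6	0.05	xyp_vs_model
CCL4	1.1	0.4	xyp_vs_model
NFKBIA	2.5	0.03	xyp_vs_model
NR3C1	1.0	0.9	xyp_vs_model
ANXA1	1.7	0.06	xyp_vs_model
DUSP1	0.5	0.04	xyp_vs_model
PTPN6	1.2	0.5	xyp_vs_model
SRC	0.9	0.7	xyp_vs_model
ICAM1	1.8	0.07	xyp_vs_model
MMP9	2.0	0.02	xyp_vs_model
TSC22D3	0.4	0.01	xyp_vs_model
CYP1A1	1.0	0.95	xyp_vs_model
PTGS1	2.4	0.01	ktp_vs_model
PTGS2	1.8	0.04	ktp_vs_model
ALOX5	1.2	0.3	ktp_vs_model
CXCL8	0.5	0.09	ktp_vs_model
IL2	0.55	0.02	ktp_vs_model
CCL4	1.6	0.09	ktp_vs_model
NFKBIA	2.1	0.02	ktp_vs_model
NR3C1	0.95	0.8	ktp_vs_model
ANXA1	0.6	0.08	ktp_vs_model
DUSP1	0.45	0.03	ktp_vs_model
PTPN6	1.0	0.99	ktp_vs_model
SRC	1.4	0.2	ktp_vs_model
ICAM1	0.5	0.05	ktp_vs_model
MMP9	0.6	0.06	ktp_vs_model
TSC22D3	2.2	0.01	ktp_vs_model
CYP1A1	1.05	0.9	ktp_vs_model
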