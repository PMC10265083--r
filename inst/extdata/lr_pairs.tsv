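pair_id	ligand	receptor
RSPO3_LGR4	RSPO3	LGR4
NECTIN2_CD226	NECTIN2	CD226
JAG2_NOTCH1	JAG2	NOTCH1
CSF1_SIRPA	CSF1	SIRPA
CXCL12_CXCR4	CXCL12	CXCR4
KITLG_KIT	KITLG	KIT
BMP4_BMPR1B	BMP4	BMPR1B
GDNF_GFRA1	GDNF	GFRA1
FGF8_FGFR3	FGF8	FGFR3
INHBB_ACVR2A	INHBB	ACVR2A
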