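cell_type	gene
SSC	UTF1
SSC	GFRA1
SSC	ID4
SSC	PIWIL4
SSC	LIN28A
Diff.ing SPG	KIT
Diff.ing SPG	DMRT1
Diff.ing SPG	SOHLH1
Diff.ing SPG	UCHL1
Diff.ing SPG	DNMT3B
Diff.ed SPG	SOHLH2
Diff.ed SPG	STRA8
Diff.ed SPG	DMRTB1
Diff.ed SPG	SYCP2L
Diff.ed SPG	RHOXF1
L	SYCP3
L	PRDM9
L	SCML1
L	SPO11
L	MEIOB
Z	SYCE1
Z	TEX101
Z	LY6K
Z	SPATA22
Z	RAD51AP2
P	PIWIL1
P	CCDC112
P	TDRG1
P	ADAM2
P	SPAG6
D	CCNA1
D	MLH3
D	OVOL2
D	CLGN
D	HSPA2
SPC7	SUN5
SPC7	SPATA4
SPC7	C9ORF116
SPC7	TEX29
SPC7	SPACA4
RS	PRM1
RS	PRM2
RS	TNP1
RS	ACR
RS	SPACA1
ST	WT1
ST	SOX9
ST	AMH
ST	CLU
ST	CITED1
MIX	ACTA2
MIX	MYH11
MIX	CYP17A1
MIX	STAR
MIX	DLK1
tMphi	CD68
tMphi	CD163
tMphi	TYROBP
tMphi	C1QA
tMphi	LYZ
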