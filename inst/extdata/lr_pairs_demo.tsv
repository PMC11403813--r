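ligand	receptor	source
TGFB1	TGFBR1&TGFBR2	curated_demo
TGFB2	TGFBR1&TGFBR2	curated_demo
TGFB3	TGFBR1&TGFBR2	curated_demo
CD74	MIF	curated_demo
MIF	CD74&CXCR4	curated_demo
IL2	IL2RA&IL2RB&IL2RG	curated_demo
IL4	IL4R&IL2RG	curated_demo
IL6	IL6R&IL6ST	curated_demo
IL10	IL10RA&IL10RB	curated_demo
IL15	IL15RA&IL2RB&IL2RG	curated_demo
TNF	TNFRSF1A	curated_demo
TNF	TNFRSF1B	curated_demo
IFNG	IFNGR1&IFNGR2	curated_demo
EGF	EGFR	curated_demo
HBEGF	EGFR	curated_demo
TGFA	EGFR	curated_demo
VEGFA	KDR	curated_demo
VEGFA	FLT1	curated_demo
VEGFB	FLT1	curated_demo
PGF	FLT1	curated_demo
FGF2	FGFR1	curated_demo
FGF2	FGFR2	curated_demo
FGF7	FGFR2	curated_demo
HGF	MET	curated_demo
IGF1	IGF1R	curated_demo
IGF2	IGF1R	curated_demo
PDGFA	PDGFRA	curated_demo
PDGFB	PDGFRB	curated_demo
CXCL12	CXCR4	curated_demo
CCL2	CCR2	curated_demo
CCL5	CCR5	curated_demo
CCL19	CCR7	curated_demo
CCL21	CCR7	curated_demo
CX3CL1	CX3CR1	curated_demo
DLL1	NOTCH1	curated_demo
DLL4	NOTCH1	curated_demo
JAG1	NOTCH1	curated_demo
JAG1	NOTCH2	curated_demo
WNT3A	FZD1&LRP6	curated_demo
WNT5A	FZD2&LRP5	curated_demo
BMP2	BMPR1A&BMPR2	curated_demo
BMP4	BMPR1A&BMPR2	curated_demo
ANGPT1	TEK	curated_demo
EFNA1	EPHA2	curated_demo
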