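gene	moi	chromosome	category	panel_version
PAX2	AD	10	CAKUT	1
HNF1B	AD	17	CAKUT	1
EYA1	AD	8	CAKUT	1
GREB1L	AD	18	CAKUT	1
CHD7	AD	8	CAKUT	1
FRAS1	AR	4	CAKUT	1
ITGA8	AR	10	CAKUT	1
SALL1	AD	16	CAKUT	1
PKD1	AD	16	ciliopathy	1
PKD2	AD	4	ciliopathy	1
PKHD1	AR	6	ciliopathy	1
NPHP1	AR	2	ciliopathy	1
TMEM67	AR	8	ciliopathy	1
CEP290	AR	12	ciliopathy	1
IFT140	AD	16	ciliopathy	1
BBS1	AR	11	ciliopathy	1
COL4A5	XLD	X	glomerulopathy	1
COL4A3	AR	2	glomerulopathy	1
COL4A4	AR	2	glomerulopathy	1
NPHS1	AR	19	glomerulopathy	1
NPHS2	AR	1	glomerulopathy	1
WT1	AD	11	glomerulopathy	1
TRPC6	AD	11	glomerulopathy	1
INF2	AD	14	glomerulopathy	1
LMX1B	AD	9	glomerulopathy	1
CFH	AD	1	glomerulopathy	1
CUBN	AR	10	glomerulopathy	1
CUBN	AD	10	glomerulopathy	1
AGXT	AR	2	nephrolithiasis	1
SLC3A1	AR	2	nephrolithiasis	1
SLC7A9	AR	19	nephrolithiasis	1
ADCY10	AD	1	nephrolithiasis	1
CLCN5	XLR	X	nephrolithiasis	1
CYP24A1	AR	20	nephrolithiasis	1
SLC34A1	AD	5	nephrolithiasis	1
GRHPR	AR	9	nephrolithiasis	1
SLC12A3	AR	16	tubulopathy	1
SLC12A1	AR	15	tubulopathy	1
CLCNKB	AR	1	tubulopathy	1
BSND	AR	1	tubulopathy	1
KCNJ1	AR	11	tubulopathy	1
CTNS	AR	17	tubulopathy	1
OCRL	XLR	X	tubulopathy	1
AVPR2	XLR	X	tubulopathy	1
UMOD	AD	16	tubulopathy	1
CASR	AD	3	tubulopathy	1
TSC1	AD	9	other	1
TSC2	AD	16	other	1
JAG1	AD	20	other	1
GATA3	AD	10	other	1
BBS10	AR	12	other	1
NPHP3	AR	3	other	1
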