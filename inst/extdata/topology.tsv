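res	atom	p1	p2	p3	bond	angle	tors	offset
*	N	-C	-CA	-N	1.329	116.2	psi_prev	0
*	CA	N	-C	-CA	1.458	121.7	omega	0
*	C	CA	N	-C	1.525	111.2	phi	0
*	O	C	CA	N	1.231	120.8	psi	180
*	CB	CA	N	C	1.530	110.5	fixed	CHIRAL
SER	OG	CB	CA	N	1.417	111.1	chi1	0
CYS	SG	CB	CA	N	1.808	113.8	chi1	0
THR	OG1	CB	CA	N	1.433	109.6	chi1	0
THR	CG2	CB	CA	N	1.521	110.5	chi1	-120
VAL	CG1	CB	CA	N	1.521	110.5	chi1	0
VAL	CG2	CB	CA	N	1.521	110.5	chi1	120
LEU	CG	CB	CA	N	1.530	116.3	chi1	0
LEU	CD1	CG	CB	CA	1.521	110.7	chi2	0
LEU	CD2	CG	CB	CA	1.521	110.7	chi2	120
ILE	CG1	CB	CA	N	1.530	110.4	chi1	0
ILE	CG2	CB	CA	N	1.521	110.5	chi1	-120
ILE	CD1	CG1	CB	CA	1.513	113.8	chi2	0
MET	CG	CB	CA	N	1.520	114.1	chi1	0
MET	SD	CG	CB	CA	1.803	112.7	chi2	0
MET	CE	SD	CG	CB	1.791	100.9	chi3	0
PRO	CG	CB	CA	N	1.492	104.5	fixed	30
PRO	CD	CG	CB	CA	1.503	106.0	fixed	-35
ASP	CG	CB	CA	N	1.516	112.6	chi1	0
ASP	OD1	CG	CB	CA	1.249	118.4	chi2	0
ASP	OD2	CG	CB	CA	1.249	118.4	chi2	180
ASN	CG	CB	CA	N	1.516	112.6	chi1	0
ASN	OD1	CG	CB	CA	1.231	120.8	chi2	0
ASN	ND2	CG	CB	CA	1.328	116.4	chi2	180
GLU	CG	CB	CA	N	1.520	114.1	chi1	0
GLU	CD	CG	CB	CA	1.516	112.6	chi2	0
GLU	OE1	CD	CG	CB	1.249	118.4	chi3	0
GLU	OE2	CD	CG	CB	1.249	118.4	chi3	180
GLN	CG	CB	CA	N	1.520	114.1	chi1	0
GLN	CD	CG	CB	CA	1.516	112.6	chi2	0
GLN	OE1	CD	CG	CB	1.231	120.8	chi3	0
GLN	NE2	CD	CG	CB	1.328	116.4	chi3	180
LYS	CG	CB	CA	N	1.520	114.1	chi1	0
LYS	CD	CG	CB	CA	1.520	111.3	chi2	0
LYS	CE	CD	CG	CB	1.520	111.3	chi3	0
LYS	NZ	CE	CD	CG	1.489	111.9	chi4	0
ARG	CG	CB	CA	N	1.520	114.1	chi1	0
ARG	CD	CG	CB	CA	1.520	111.3	chi2	0
ARG	NE	CD	CG	CB	1.461	112.0	chi3	0
ARG	CZ	NE	CD	CG	1.329	124.2	chi4	0
ARG	NH1	CZ	NE	CD	1.326	120.0	chi5	0
ARG	NH2	CZ	NE	CD	1.326	120.0	chi5	180
HIS	CG	CB	CA	N	1.497	113.8	chi1	0
HIS	ND1	CG	CB	CA	1.378	122.7	chi2	0
HIS	CD2	CG	CB	CA	1.354	131.2	chi2	180
HIS	CE1	ND1	CG	CB	1.321	109.2	fixed	180
HIS	NE2	CE1	ND1	CG	1.321	108.2	fixed	0
PHE	CG	CB	CA	N	1.502	113.8	chi1	0
PHE	CD1	CG	CB	CA	1.391	120.8	chi2	0
PHE	CD2	CG	CB	CA	1.391	120.8	chi2	180
PHE	CE1	CD1	CG	CB	1.391	120.1	fixed	180
PHE	CE2	CD2	CG	CB	1.391	120.1	fixed	180
PHE	CZ	CE1	CD1	CG	1.391	120.0	fixed	0
TYR	CG	CB	CA	N	1.502	113.8	chi1	0
TYR	CD1	CG	CB	CA	1.391	120.8	chi2	0
TYR	CD2	CG	CB	CA	1.391	120.8	chi2	180
TYR	CE1	CD1	CG	CB	1.391	120.1	fixed	180
TYR	CE2	CD2	CG	CB	1.391	120.1	fixed	180
TYR	CZ	CE1	CD1	CG	1.391	120.0	fixed	0
TYR	OH	CZ	CE1	CD1	1.377	119.8	fixed	180
TRP	CG	CB	CA	N	1.498	113.6	chi1	0
TRP	CD1	CG	CB	CA	1.365	126.9	chi2	0
TRP	CD2	CG	CB	CA	1.433	126.7	chi2	180
TRP	NE1	CD1	CG	CB	1.374	110.2	fixed	180
TRP	CE2	CD2	CG	CB	1.409	107.2	fixed	180
TRP	CE3	CD2	CG	CB	1.398	133.9	fixed	0
TRP	CZ2	CE2	CD2	CG	1.394	122.4	fixed	180
TRP	CZ3	CE3	CD2	CG	1.382	118.6	fixed	180
TRP	CH2	CZ2	CE2	CD2	1.368	117.5	fixed	0
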