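res	chi	a1	a2	a3	a4	rotatable
ARG	1	N	CA	CB	CG	1
ARG	2	CA	CB	CG	CD	1
ARG	3	CB	CG	CD	NE	1
ARG	4	CG	CD	NE	CZ	1
ARG	5	CD	NE	CZ	NH1	1
ASN	1	N	CA	CB	CG	1
ASN	2	CA	CB	CG	OD1	1
ASP	1	N	CA	CB	CG	1
ASP	2	CA	CB	CG	OD1	1
CYS	1	N	CA	CB	SG	1
GLN	1	N	CA	CB	CG	1
GLN	2	CA	CB	CG	CD	1
GLN	3	CB	CG	CD	OE1	1
GLU	1	N	CA	CB	CG	1
GLU	2	CA	CB	CG	CD	1
GLU	3	CB	CG	CD	OE1	1
HIS	1	N	CA	CB	CG	1
HIS	2	CA	CB	CG	ND1	1
ILE	1	N	CA	CB	CG1	1
ILE	2	CA	CB	CG1	CD1	1
LEU	1	N	CA	CB	CG	1
LEU	2	CA	CB	CG	CD1	1
LYS	1	N	CA	CB	CG	1
LYS	2	CA	CB	CG	CD	1
LYS	3	CB	CG	CD	CE	1
LYS	4	CG	CD	CE	NZ	1
MET	1	N	CA	CB	CG	1
MET	2	CA	CB	CG	SD	1
MET	3	CB	CG	SD	CE	1
PHE	1	N	CA	CB	CG	1
PHE	2	CA	CB	CG	CD1	1
PRO	1	N	CA	CB	CG	0
PRO	2	CA	CB	CG	CD	0
SER	1	N	CA	CB	OG	1
THR	1	N	CA	CB	OG1	1
TRP	1	N	CA	CB	CG	1
TRP	2	CA	CB	CG	CD1	1
TYR	1	N	CA	CB	CG	1
TYR	2	CA	CB	CG	CD1	1
VAL	1	N	CA	CB	CG1	1
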