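res	atom	charge	donor	acceptor	hybrid	antecedent
*	N	0	1	0	sp2	CA
*	O	0	0	1	sp2	C
*	OXT	0	0	1	sp2	C
PRO	N	0	0	0	sp2	CA
ASP	OD1	-0.5	0	1	sp2	CG
ASP	OD2	-0.5	0	1	sp2	CG
GLU	OE1	-0.5	0	1	sp2	CD
GLU	OE2	-0.5	0	1	sp2	CD
LYS	NZ	1.0	1	0	sp3	CE
ARG	NE	0	1	0	sp2	CZ
ARG	NH1	0.5	1	0	sp2	CZ
ARG	NH2	0.5	1	0	sp2	CZ
ASN	OD1	0	0	1	sp2	CG
ASN	ND2	0	1	0	sp2	CG
GLN	OE1	0	0	1	sp2	CD
GLN	NE2	0	1	0	sp2	CD
SER	OG	0	1	1	sp3	CB
THR	OG1	0	1	1	sp3	CB
TYR	OH	0	1	1	sp2	CZ
HIS	ND1	0	0	1	sp2	CG
HIS	NE2	0	1	0	sp2	CE1
TRP	NE1	0	1	0	sp2	CD1
CYS	SG	0	1	0	sp3	CB
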