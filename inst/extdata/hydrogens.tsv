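res	hname	parent	p2	p3	bond	angle	tors
SER	HG	OG	CB	CA	0.96	109.5	180
THR	HG1	OG1	CB	CA	0.96	109.5	180
TYR	HH	OH	CZ	CE1	0.96	110.0	180
CYS	HG	SG	CB	CA	1.34	96.0	180
LYS	HZ1	NZ	CE	CD	1.01	109.5	180
LYS	HZ2	NZ	CE	CD	1.01	109.5	60
LYS	HZ3	NZ	CE	CD	1.01	109.5	-60
ARG	HE	NE	CZ	CD	1.01	118.0	180
ARG	HH11	NH1	CZ	NE	1.01	120.0	0
ARG	HH12	NH1	CZ	NE	1.01	120.0	180
ARG	HH21	NH2	CZ	NE	1.01	120.0	0
ARG	HH22	NH2	CZ	NE	1.01	120.0	180
ASN	HD21	ND2	CG	OD1	1.01	120.0	180
ASN	HD22	ND2	CG	OD1	1.01	120.0	0
GLN	HE21	NE2	CD	OE1	1.01	120.0	180
GLN	HE22	NE2	CD	OE1	1.01	120.0	0
HIS	HE2	NE2	CE1	ND1	1.01	125.0	180
TRP	HE1	NE1	CD1	CG	1.01	125.0	180
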