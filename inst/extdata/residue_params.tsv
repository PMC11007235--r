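res	c_polar	c_hydrophobic	c_vdw	s_entropy	w_scv
ALA	0.00	0.50	-0.80	0.00	1
ARG	-1.40	0.30	-2.20	2.20	1
ASN	-0.85	0.10	-1.40	1.20	1
ASP	-1.25	0.10	-1.30	1.10	1
CYS	-0.10	1.00	-1.20	0.70	1
GLN	-0.90	0.20	-1.70	1.70	1
GLU	-1.30	0.20	-1.60	1.60	1
GLY	0.00	0.30	-0.50	0.00	1
HIS	-0.60	0.60	-1.90	1.20	1
ILE	0.00	1.70	-1.90	0.90	1
LEU	0.00	1.60	-1.90	1.00	1
LYS	-1.10	0.40	-1.90	2.00	1
MET	-0.05	1.30	-2.00	1.60	1
PHE	0.00	1.90	-2.40	1.20	1
PRO	-0.20	0.70	-1.40	0.00	1
SER	-0.45	0.10	-0.90	0.90	1
THR	-0.40	0.30	-1.20	0.80	1
TRP	-0.30	1.90	-2.90	1.40	1
TYR	-0.35	1.30	-2.50	1.40	1
VAL	0.00	1.40	-1.60	0.60	1
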