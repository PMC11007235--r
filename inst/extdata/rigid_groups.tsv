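res	group	atoms
PHE	ring	CG,CD1,CD2,CE1,CE2,CZ
TYR	ring	CG,CD1,CD2,CE1,CE2,CZ,OH
HIS	ring	CG,ND1,CD2,CE1,NE2
TRP	ring	CG,CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2
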