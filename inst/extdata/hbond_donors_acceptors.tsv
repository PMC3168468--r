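residue	atom	role
*	N	donor
*	O	acceptor
*	OXT	acceptor
SER	OG	donor
SER	OG	acceptor
THR	OG1	donor
THR	OG1	acceptor
TYR	OH	donor
TYR	OH	acceptor
CYS	SG	donor
ASN	ND2	donor
ASN	OD1	acceptor
GLN	NE2	donor
GLN	OE1	acceptor
HIS	ND1	donor
HIS	ND1	acceptor
HIS	NE2	donor
HIS	NE2	acceptor
LYS	NZ	donor
ARG	NE	donor
ARG	NH1	donor
ARG	NH2	donor
TRP	NE1	donor
ASP	OD1	acceptor
ASP	OD2	acceptor
GLU	OE1	acceptor
GLU	OE2	acceptor
MET	SD	acceptor
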