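res_name	atom_name	classes
ALA	N	donor
ALA	CA	hydrophobic
ALA	C	hydrophobic
ALA	O	acceptor
ALA	OXT	negative,acceptor
ALA	CB	hydrophobic
ARG	N	donor
ARG	CA	hydrophobic
ARG	C	hydrophobic
ARG	O	acceptor
ARG	OXT	negative,acceptor
ARG	CB	hydrophobic
ARG	CG	hydrophobic
ARG	CD	hydrophobic
ARG	NE	positive,donor
ARG	CZ	hydrophobic
ARG	NH1	positive,donor
ARG	NH2	positive,donor
ASN	N	donor
ASN	CA	hydrophobic
ASN	C	hydrophobic
ASN	O	acceptor
ASN	OXT	negative,acceptor
ASN	CB	hydrophobic
ASN	CG	hydrophobic
ASN	OD1	acceptor
ASN	ND2	donor
ASP	N	donor
ASP	CA	hydrophobic
ASP	C	hydrophobic
ASP	O	acceptor
ASP	OXT	negative,acceptor
ASP	CB	hydrophobic
ASP	CG	hydrophobic
ASP	OD1	negative,acceptor
ASP	OD2	negative,acceptor
CYS	N	donor
CYS	CA	hydrophobic
CYS	C	hydrophobic
CYS	O	acceptor
CYS	OXT	negative,acceptor
CYS	CB	hydrophobic
CYS	SG	sulfur
GLN	N	donor
GLN	CA	hydrophobic
GLN	C	hydrophobic
GLN	O	acceptor
GLN	OXT	negative,acceptor
GLN	CB	hydrophobic
GLN	CG	hydrophobic
GLN	CD	hydrophobic
GLN	OE1	acceptor
GLN	NE2	donor
GLU	N	donor
GLU	CA	hydrophobic
GLU	C	hydrophobic
GLU	O	acceptor
GLU	OXT	negative,acceptor
GLU	CB	hydrophobic
GLU	CG	hydrophobic
GLU	CD	hydrophobic
GLU	OE1	negative,acceptor
GLU	OE2	negative,acceptor
GLY	N	donor
GLY	CA	hydrophobic
GLY	C	hydrophobic
GLY	O	acceptor
GLY	OXT	negative,acceptor
HIS	N	donor
HIS	CA	hydrophobic
HIS	C	hydrophobic
HIS	O	acceptor
HIS	OXT	negative,acceptor
HIS	CB	hydrophobic
HIS	CG	aromatic
HIS	ND1	positive,acceptor,donor,aromatic
HIS	CD2	aromatic
HIS	CE1	aromatic
HIS	NE2	positive,acceptor,donor,aromatic
ILE	N	donor
ILE	CA	hydrophobic
ILE	C	hydrophobic
ILE	O	acceptor
ILE	OXT	negative,acceptor
ILE	CB	hydrophobic
ILE	CG1	hydrophobic
ILE	CG2	hydrophobic
ILE	CD1	hydrophobic
LEU	N	donor
LEU	CA	hydrophobic
LEU	C	hydrophobic
LEU	O	acceptor
LEU	OXT	negative,acceptor
LEU	CB	hydrophobic
LEU	CG	hydrophobic
LEU	CD1	hydrophobic
LEU	CD2	hydrophobic
LYS	N	donor
LYS	CA	hydrophobic
LYS	C	hydrophobic
LYS	O	acceptor
LYS	OXT	negative,acceptor
LYS	CB	hydrophobic
LYS	CG	hydrophobic
LYS	CD	hydrophobic
LYS	CE	hydrophobic
LYS	NZ	positive,donor
MET	N	donor
MET	CA	hydrophobic
MET	C	hydrophobic
MET	O	acceptor
MET	OXT	negative,acceptor
MET	CB	hydrophobic
MET	CG	hydrophobic
MET	SD	sulfur
MET	CE	hydrophobic
PHE	N	donor
PHE	CA	hydrophobic
PHE	C	hydrophobic
PHE	O	acceptor
PHE	OXT	negative,acceptor
PHE	CB	hydrophobic
PHE	CG	aromatic
PHE	CD1	aromatic
PHE	CD2	aromatic
PHE	CE1	aromatic
PHE	CE2	aromatic
PHE	CZ	aromatic
PRO	N	neutral
PRO	CA	hydrophobic
PRO	C	hydrophobic
PRO	O	acceptor
PRO	OXT	negative,acceptor
PRO	CB	hydrophobic
PRO	CG	hydrophobic
PRO	CD	hydrophobic
SER	N	donor
SER	CA	hydrophobic
SER	C	hydrophobic
SER	O	acceptor
SER	OXT	negative,acceptor
SER	CB	hydrophobic
SER	OG	acceptor,donor
THR	N	donor
THR	CA	hydrophobic
THR	C	hydrophobic
THR	O	acceptor
THR	OXT	negative,acceptor
THR	CB	hydrophobic
THR	OG1	acceptor,donor
THR	CG2	hydrophobic
TRP	N	donor
TRP	CA	hydrophobic
TRP	C	hydrophobic
TRP	O	acceptor
TRP	OXT	negative,acceptor
TRP	CB	hydrophobic
TRP	CG	aromatic
TRP	CD1	aromatic
TRP	CD2	aromatic
TRP	NE1	donor,aromatic
TRP	CE2	aromatic
TRP	CE3	aromatic
TRP	CZ2	aromatic
TRP	CZ3	aromatic
TRP	CH2	aromatic
TYR	N	donor
TYR	CA	hydrophobic
TYR	C	hydrophobic
TYR	O	acceptor
TYR	OXT	negative,acceptor
TYR	CB	hydrophobic
TYR	CG	aromatic
TYR	CD1	aromatic
TYR	CD2	aromatic
TYR	CE1	aromatic
TYR	CE2	aromatic
TYR	CZ	aromatic
TYR	OH	acceptor,donor
VAL	N	donor
VAL	CA	hydrophobic
VAL	C	hydrophobic
VAL	O	acceptor
VAL	OXT	negative,acceptor
VAL	CB	hydrophobic
VAL	CG1	hydrophobic
VAL	CG2	hydrophobic
*	C	hydrophobic
*	N	donor
*	O	acceptor
*	S	sulfur
*	P	neutral
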