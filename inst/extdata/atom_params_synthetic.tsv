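# Synthetic simplified CHARMM-style heavy-atom parameter set (v1).
# epsilon kcal/mol, rmin_half Angstrom, charge e.
# Partial charges sum exactly to each residue's formal charge (OXT excluded).
residue	atom	epsilon	rmin_half	charge
ALA	N	0.20	1.85	-0.47
ALA	CA	0.08	2.00	0.07
ALA	C	0.08	2.00	0.51
ALA	O	0.12	1.70	-0.51
ALA	OXT	0.12	1.70	0.00
ALA	CB	0.08	2.00	0.40
ARG	N	0.20	1.85	-0.47
ARG	CA	0.08	2.00	0.07
ARG	C	0.08	2.00	0.51
ARG	O	0.12	1.70	-0.51
ARG	OXT	0.12	1.70	0.00
ARG	CB	0.08	2.00	0.40
ARG	CG	0.08	2.00	0.00
ARG	CD	0.08	2.00	0.00
ARG	NE	0.20	1.85	0.00
ARG	CZ	0.08	2.00	0.00
ARG	NH1	0.20	1.85	0.50
ARG	NH2	0.20	1.85	0.50
ASN	N	0.20	1.85	-0.47
ASN	CA	0.08	2.00	0.07
ASN	C	0.08	2.00	0.51
ASN	O	0.12	1.70	-0.51
ASN	OXT	0.12	1.70	0.00
ASN	CB	0.08	2.00	0.40
ASN	CG	0.08	2.00	0.00
ASN	OD1	0.12	1.70	0.00
ASN	ND2	0.20	1.85	0.00
ASP	N	0.20	1.85	-0.47
ASP	CA	0.08	2.00	0.07
ASP	C	0.08	2.00	0.51
ASP	O	0.12	1.70	-0.51
ASP	OXT	0.12	1.70	0.00
ASP	CB	0.08	2.00	0.40
ASP	CG	0.08	2.00	0.00
ASP	OD1	0.12	1.70	-0.50
ASP	OD2	0.12	1.70	-0.50
CYS	N	0.20	1.85	-0.47
CYS	CA	0.08	2.00	0.07
CYS	C	0.08	2.00	0.51
CYS	O	0.12	1.70	-0.51
CYS	OXT	0.12	1.70	0.00
CYS	CB	0.08	2.00	0.40
CYS	SG	0.45	2.00	0.00
GLN	N	0.20	1.85	-0.47
GLN	CA	0.08	2.00	0.07
GLN	C	0.08	2.00	0.51
GLN	O	0.12	1.70	-0.51
GLN	OXT	0.12	1.70	0.00
GLN	CB	0.08	2.00	0.40
GLN	CG	0.08	2.00	0.00
GLN	CD	0.08	2.00	0.00
GLN	OE1	0.12	1.70	0.00
GLN	NE2	0.20	1.85	0.00
GLU	N	0.20	1.85	-0.47
GLU	CA	0.08	2.00	0.07
GLU	C	0.08	2.00	0.51
GLU	O	0.12	1.70	-0.51
GLU	OXT	0.12	1.70	0.00
GLU	CB	0.08	2.00	0.40
GLU	CG	0.08	2.00	0.00
GLU	CD	0.08	2.00	0.00
GLU	OE1	0.12	1.70	-0.50
GLU	OE2	0.12	1.70	-0.50
GLY	N	0.20	1.85	-0.47
GLY	CA	0.08	2.00	0.47
GLY	C	0.08	2.00	0.51
GLY	O	0.12	1.70	-0.51
GLY	OXT	0.12	1.70	0.00
HIS	N	0.20	1.85	-0.47
HIS	CA	0.08	2.00	0.07
HIS	C	0.08	2.00	0.51
HIS	O	0.12	1.70	-0.51
HIS	OXT	0.12	1.70	0.00
HIS	CB	0.08	2.00	0.40
HIS	CG	0.08	2.00	0.00
HIS	ND1	0.20	1.85	0.00
HIS	CD2	0.08	2.00	0.00
HIS	CE1	0.08	2.00	0.00
HIS	NE2	0.20	1.85	0.00
ILE	N	0.20	1.85	-0.47
ILE	CA	0.08	2.00	0.07
ILE	C	0.08	2.00	0.51
ILE	O	0.12	1.70	-0.51
ILE	OXT	0.12	1.70	0.00
ILE	CB	0.08	2.00	0.40
ILE	CG1	0.08	2.00	0.00
ILE	CG2	0.08	2.00	0.00
ILE	CD1	0.08	2.00	0.00
LEU	N	0.20	1.85	-0.47
LEU	CA	0.08	2.00	0.07
LEU	C	0.08	2.00	0.51
LEU	O	0.12	1.70	-0.51
LEU	OXT	0.12	1.70	0.00
LEU	CB	0.08	2.00	0.40
LEU	CG	0.08	2.00	0.00
LEU	CD1	0.08	2.00	0.00
LEU	CD2	0.08	2.00	0.00
LYS	N	0.20	1.85	-0.47
LYS	CA	0.08	2.00	0.07
LYS	C	0.08	2.00	0.51
LYS	O	0.12	1.70	-0.51
LYS	OXT	0.12	1.70	0.00
LYS	CB	0.08	2.00	0.40
LYS	CG	0.08	2.00	0.00
LYS	CD	0.08	2.00	0.00
LYS	CE	0.08	2.00	0.00
LYS	NZ	0.20	1.85	1.00
MET	N	0.20	1.85	-0.47
MET	CA	0.08	2.00	0.07
MET	C	0.08	2.00	0.51
MET	O	0.12	1.70	-0.51
MET	OXT	0.12	1.70	0.00
MET	CB	0.08	2.00	0.40
MET	CG	0.08	2.00	0.00
MET	SD	0.45	2.00	0.00
MET	CE	0.08	2.00	0.00
PHE	N	0.20	1.85	-0.47
PHE	CA	0.08	2.00	0.07
PHE	C	0.08	2.00	0.51
PHE	O	0.12	1.70	-0.51
PHE	OXT	0.12	1.70	0.00
PHE	CB	0.08	2.00	0.40
PHE	CG	0.08	2.00	0.00
PHE	CD1	0.08	2.00	0.00
PHE	CD2	0.08	2.00	0.00
PHE	CE1	0.08	2.00	0.00
PHE	CE2	0.08	2.00	0.00
PHE	CZ	0.08	2.00	0.00
PRO	N	0.20	1.85	-0.47
PRO	CA	0.08	2.00	0.07
PRO	C	0.08	2.00	0.51
PRO	O	0.12	1.70	-0.51
PRO	OXT	0.12	1.70	0.00
PRO	CB	0.08	2.00	0.40
PRO	CG	0.08	2.00	0.00
PRO	CD	0.08	2.00	0.00
SER	N	0.20	1.85	-0.47
SER	CA	0.08	2.00	0.07
SER	C	0.08	2.00	0.51
SER	O	0.12	1.70	-0.51
SER	OXT	0.12	1.70	0.00
SER	CB	0.08	2.00	0.40
SER	OG	0.12	1.70	0.00
THR	N	0.20	1.85	-0.47
THR	CA	0.08	2.00	0.07
THR	C	0.08	2.00	0.51
THR	O	0.12	1.70	-0.51
THR	OXT	0.12	1.70	0.00
THR	CB	0.08	2.00	0.40
THR	OG1	0.12	1.70	0.00
THR	CG2	0.08	2.00	0.00
TRP	N	0.20	1.85	-0.47
TRP	CA	0.08	2.00	0.07
TRP	C	0.08	2.00	0.51
TRP	O	0.12	1.70	-0.51
TRP	OXT	0.12	1.70	0.00
TRP	CB	0.08	2.00	0.40
TRP	CG	0.08	2.00	0.00
TRP	CD1	0.08	2.00	0.00
TRP	CD2	0.08	2.00	0.00
TRP	NE1	0.20	1.85	0.00
TRP	CE2	0.08	2.00	0.00
TRP	CE3	0.08	2.00	0.00
TRP	CZ2	0.08	2.00	0.00
TRP	CZ3	0.08	2.00	0.00
TRP	CH2	0.08	2.00	0.00
TYR	N	0.20	1.85	-0.47
TYR	CA	0.08	2.00	0.07
TYR	C	0.08	2.00	0.51
TYR	O	0.12	1.70	-0.51
TYR	OXT	0.12	1.70	0.00
TYR	CB	0.08	2.00	0.40
TYR	CG	0.08	2.00	0.00
TYR	CD1	0.08	2.00	0.00
TYR	CD2	0.08	2.00	0.00
TYR	CE1	0.08	2.00	0.00
TYR	CE2	0.08	2.00	0.00
TYR	CZ	0.08	2.00	0.00
TYR	OH	0.12	1.70	0.00
VAL	N	0.20	1.85	-0.47
VAL	CA	0.08	2.00	0.07
VAL	C	0.08	2.00	0.51
VAL	O	0.12	1.70	-0.51
VAL	OXT	0.12	1.70	0.00
VAL	CB	0.08	2.00	0.40
VAL	CG1	0.08	2.00	0.00
VAL	CG2	0.08	2.00	0.00
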