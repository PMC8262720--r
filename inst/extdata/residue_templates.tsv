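# nciprofiler residue feature templates, version 1
# residue	atom	feature	arg
# feature: donor (arg = hydrogens expected), acceptor, pos, neg,
#          ring1/ring2 (aromatic ring membership), hydrophobic
# Backbone amide N (donor) and carbonyl O (acceptor) of amino acids are
# implicit and handled in code; side chains and full nucleotides listed here.
ALA	CB	hydrophobic
ARG	NE	donor	1
ARG	NH1	donor	2
ARG	NH2	donor	2
ARG	NH1	pos
ARG	NH2	pos
ARG	NE	pos
ARG	CZ	pos
ARG	CB	hydrophobic
ARG	CG	hydrophobic
ASN	ND2	donor	2
ASN	OD1	acceptor
ASN	CB	hydrophobic
ASP	OD1	acceptor
ASP	OD2	acceptor
ASP	OD1	neg
ASP	OD2	neg
ASP	CB	hydrophobic
CYS	SG	donor	1
GLN	NE2	donor	2
GLN	OE1	acceptor
GLN	CB	hydrophobic
GLN	CG	hydrophobic
GLU	OE1	acceptor
GLU	OE2	acceptor
GLU	OE1	neg
GLU	OE2	neg
GLU	CB	hydrophobic
GLU	CG	hydrophobic
HIS	NE2	donor	1
HIS	ND1	acceptor
HIS	CG	ring1
HIS	ND1	ring1
HIS	CD2	ring1
HIS	CE1	ring1
HIS	NE2	ring1
HIS	CB	hydrophobic
ILE	CB	hydrophobic
ILE	CG1	hydrophobic
ILE	CG2	hydrophobic
ILE	CD1	hydrophobic
LEU	CB	hydrophobic
LEU	CG	hydrophobic
LEU	CD1	hydrophobic
LEU	CD2	hydrophobic
LYS	NZ	donor	3
LYS	NZ	pos
LYS	CB	hydrophobic
LYS	CG	hydrophobic
LYS	CD	hydrophobic
MET	CB	hydrophobic
PHE	CG	ring1
PHE	CD1	ring1
PHE	CD2	ring1
PHE	CE1	ring1
PHE	CE2	ring1
PHE	CZ	ring1
PHE	CB	hydrophobic
PHE	CG	hydrophobic
PHE	CD1	hydrophobic
PHE	CD2	hydrophobic
PHE	CE1	hydrophobic
PHE	CE2	hydrophobic
PHE	CZ	hydrophobic
PRO	CB	hydrophobic
PRO	CG	hydrophobic
SER	OG	donor	1
SER	OG	acceptor
THR	OG1	donor	1
THR	OG1	acceptor
THR	CG2	hydrophobic
TRP	NE1	donor	1
TRP	CG	ring1
TRP	CD1	ring1
TRP	NE1	ring1
TRP	CE2	ring1
TRP	CD2	ring1
TRP	CD2	ring2
TRP	CE2	ring2
TRP	CZ2	ring2
TRP	CH2	ring2
TRP	CZ3	ring2
TRP	CE3	ring2
TRP	CB	hydrophobic
TRP	CG	hydrophobic
TRP	CD2	hydrophobic
TRP	CE3	hydrophobic
TRP	CZ3	hydrophobic
TRP	CH2	hydrophobic
TRP	CZ2	hydrophobic
TYR	OH	donor	1
TYR	OH	acceptor
TYR	CG	ring1
TYR	CD1	ring1
TYR	CD2	ring1
TYR	CE1	ring1
TYR	CE2	ring1
TYR	CZ	ring1
TYR	CB	hydrophobic
TYR	CG	hydrophobic
TYR	CD1	hydrophobic
TYR	CD2	hydrophobic
TYR	CE1	hydrophobic
TYR	CE2	hydrophobic
VAL	CB	hydrophobic
VAL	CG1	hydrophobic
VAL	CG2	hydrophobic
A	OP1	acceptor
A	OP2	acceptor
A	OP1	neg
A	OP2	neg
A	O4'	acceptor
A	O3'	acceptor
A	O5'	acceptor
A	O2'	donor	1
A	O2'	acceptor
A	N1	ring1
A	C2	ring1
A	N3	ring1
A	C4	ring1
A	C5	ring1
A	C6	ring1
A	C4	ring2
A	C5	ring2
A	N7	ring2
A	C8	ring2
A	N9	ring2
A	N6	donor	2
A	N1	acceptor
A	N3	acceptor
A	N7	acceptor
G	OP1	acceptor
G	OP2	acceptor
G	OP1	neg
G	OP2	neg
G	O4'	acceptor
G	O3'	acceptor
G	O5'	acceptor
G	O2'	donor	1
G	O2'	acceptor
G	N1	ring1
G	C2	ring1
G	N3	ring1
G	C4	ring1
G	C5	ring1
G	C6	ring1
G	C4	ring2
G	C5	ring2
G	N7	ring2
G	C8	ring2
G	N9	ring2
G	N1	donor	1
G	N2	donor	2
G	O6	acceptor
G	N7	acceptor
G	N3	acceptor
C	OP1	acceptor
C	OP2	acceptor
C	OP1	neg
C	OP2	neg
C	O4'	acceptor
C	O3'	acceptor
C	O5'	acceptor
C	O2'	donor	1
C	O2'	acceptor
C	N1	ring1
C	C2	ring1
C	N3	ring1
C	C4	ring1
C	C5	ring1
C	C6	ring1
C	N4	donor	2
C	O2	acceptor
C	N3	acceptor
C	C5	hydrophobic
U	OP1	acceptor
U	OP2	acceptor
U	OP1	neg
U	OP2	neg
U	O4'	acceptor
U	O3'	acceptor
U	O5'	acceptor
U	O2'	donor	1
U	O2'	acceptor
U	N1	ring1
U	C2	ring1
U	N3	ring1
U	C4	ring1
U	C5	ring1
U	C6	ring1
U	N3	donor	1
U	O2	acceptor
U	O4	acceptor
U	C5	hydrophobic
DA	OP1	acceptor
DA	OP2	acceptor
DA	OP1	neg
DA	OP2	neg
DA	O4'	acceptor
DA	O3'	acceptor
DA	O5'	acceptor
DA	C2'	hydrophobic
DA	N1	ring1
DA	C2	ring1
DA	N3	ring1
DA	C4	ring1
DA	C5	ring1
DA	C6	ring1
DA	C4	ring2
DA	C5	ring2
DA	N7	ring2
DA	C8	ring2
DA	N9	ring2
DA	N6	donor	2
DA	N1	acceptor
DA	N3	acceptor
DA	N7	acceptor
DG	OP1	acceptor
DG	OP2	acceptor
DG	OP1	neg
DG	OP2	neg
DG	O4'	acceptor
DG	O3'	acceptor
DG	O5'	acceptor
DG	C2'	hydrophobic
DG	N1	ring1
DG	C2	ring1
DG	N3	ring1
DG	C4	ring1
DG	C5	ring1
DG	C6	ring1
DG	C4	ring2
DG	C5	ring2
DG	N7	ring2
DG	C8	ring2
DG	N9	ring2
DG	N1	donor	1
DG	N2	donor	2
DG	O6	acceptor
DG	N7	acceptor
DG	N3	acceptor
DC	OP1	acceptor
DC	OP2	acceptor
DC	OP1	neg
DC	OP2	neg
DC	O4'	acceptor
DC	O3'	acceptor
DC	O5'	acceptor
DC	C2'	hydrophobic
DC	N1	ring1
DC	C2	ring1
DC	N3	ring1
DC	C4	ring1
DC	C5	ring1
DC	C6	ring1
DC	N4	donor	2
DC	O2	acceptor
DC	N3	acceptor
DC	C5	hydrophobic
DT	OP1	acceptor
DT	OP2	acceptor
DT	OP1	neg
DT	OP2	neg
DT	O4'	acceptor
DT	O3'	acceptor
DT	O5'	acceptor
DT	C2'	hydrophobic
DT	N1	ring1
DT	C2	ring1
DT	N3	ring1
DT	C4	ring1
DT	C5	ring1
DT	C6	ring1
DT	N3	donor	1
DT	O2	acceptor
DT	O4	acceptor
DT	C5	hydrophobic
DT	C7	hydrophobic
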