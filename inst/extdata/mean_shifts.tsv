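# Typical protein chemical-shift means/sd (ppm) per residue type and atom,
# rounded from public database averages; used by synthetic_shift_table().
# "*" rows are fallbacks for any residue type.
restype	atom	mean	sd
ALA	CA	53.1	1.9
ALA	CB	19.0	1.8
ARG	CA	56.8	2.3
ARG	CB	30.6	1.8
ASN	CA	53.5	1.9
ASN	CB	38.7	1.7
ASP	CA	54.7	2.0
ASP	CB	40.9	1.6
GLN	CA	56.6	2.1
GLN	CB	29.2	1.8
GLU	CA	57.4	2.1
GLU	CB	30.0	1.7
GLY	CA	45.4	1.3
HIS	CA	56.5	2.3
HIS	CB	30.2	2.1
ILE	CA	61.6	2.7
ILE	CB	38.6	2.0
LEU	CA	55.6	2.1
LEU	CB	42.3	1.9
LYS	CA	56.9	2.2
LYS	CB	32.8	1.8
MET	CA	56.1	2.2
MET	CB	32.9	2.2
PHE	CA	58.1	2.6
PHE	CB	39.9	2.1
PRO	CA	63.3	1.5
PRO	CB	31.8	1.2
SER	CA	58.7	2.1
SER	CB	63.8	1.5
THR	CA	62.2	2.6
THR	CB	69.6	1.6
TRP	CA	57.7	2.6
TRP	CB	29.9	2.0
TYR	CA	58.1	2.5
TYR	CB	39.2	2.2
VAL	CA	62.5	2.9
VAL	CB	32.7	1.8
*	C	176.4	2.0
*	N	119.0	4.0
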