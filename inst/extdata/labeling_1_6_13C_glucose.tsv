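# Sparse labeling from growth on 1,6-13C-glucose.
# LITERATURE-DERIVED DEFAULTS, USER-OVERRIDABLE: glucose C1/C6 feed CB and
# methyl positions of most amino acids, with low enrichment at CA and
# carbonyl sites.  Edit or replace to match a measured isotopomer
# distribution.
restype	atom	fraction
*	CA	0.05
*	CB	0.55
*	C	0.05
GLY	CA	0.30
SER	CB	0.60
ALA	CB	0.60
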