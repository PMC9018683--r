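# Sparse labeling from growth on 2-13C-glucose.
# LITERATURE-DERIVED DEFAULTS, USER-OVERRIDABLE: biosynthetic label routing
# places 13C predominantly at CA positions (glycolytic C2 enters the alpha
# carbon of most amino acids), with low enrichment at CB and carbonyl sites.
# Edit or replace this table to match a measured isotopomer distribution.
restype	atom	fraction
*	CA	0.60
*	CB	0.05
*	C	0.05
GLY	CA	0.55
LEU	CA	0.25
ILE	CA	0.30
VAL	CA	0.55
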