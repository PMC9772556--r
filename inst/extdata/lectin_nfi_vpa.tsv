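lectin	monosaccharide_class	nfi_control	nfi_case	fc
ConA	Mannose	0.109	0.198	1.82
GNA	Mannose	0.020	0.006	-3.34
GSL-II	GlcNAc	0.059	0.094	1.59
PHA-E	GlcNAc	0.031	0.040	1.32
DSA	GlcNAc	0.027	0.034	1.26
WGA	GlcNAc	0.083	0.031	-2.63
PTL-I	GalNAc	0.042	0.058	1.38
DBA	GalNAc	0.006	0.008	1.29
VVA	GalNAc	0.071	0.029	-2.47
ECA	Galactose	0.054	0.072	1.34
Jacalin	Galactose	0.102	0.122	1.20
MAL-I	Galactose	0.024	0.014	-1.72
BPL	Galactose	0.049	0.024	-2.06
RCA120	Galactose	0.024	0.009	-2.50
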