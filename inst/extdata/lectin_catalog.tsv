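lectin	monosaccharide_class	motifs
ConA	Mannose	high-mannose-branched
GNA	Mannose	terminal-a13-mannose
GSL-II	GlcNAc	agalacto-antennary-GlcNAc
PHA-E	GlcNAc	bisecting-GlcNAc
DSA	GlcNAc	poly-GlcNAc;type2-LacNAc
WGA	GlcNAc	sialyl-Gal-GalNAc;poly-GlcNAc
PTL-I	GalNAc	terminal-GalNAc;GalNAc-a13-Gal
DBA	GalNAc	Tn-antigen;GalNAc-a13-Gal
VVA	GalNAc	terminal-GalNAc;Tn-antigen;GalNAc-a13-Gal
ECA	Galactose	type2-LacNAc;type1-LacNAc
Jacalin	Galactose	T-antigen;Tn-antigen
MAL-I	Galactose	sialyl-Gal-GalNAc
BPL	Galactose	T-antigen;terminal-GalNAc
RCA120	Galactose	beta-Gal;type2-LacNAc;type1-LacNAc
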