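group	family	n	source
Glycosyltransferases	*	259	CAZy
Glycoside hydrolases	*	94	CAZy
Carbohydrate-binding modules	*	7	CAZy
Glycan biosynthesis and metabolism	N-Glycan biosynthesis	12	KEGG
Glycan biosynthesis and metabolism	Various types of N-glycan biosynthesis	2	KEGG
Glycan biosynthesis and metabolism	Mannose type O-glycan biosynthesis	5	KEGG
Glycan biosynthesis and metabolism	Glycosaminoglycan biosynthesis	78	KEGG
Glycan biosynthesis and metabolism	Glycosaminoglycan degradation	6	KEGG
Glycan biosynthesis and metabolism	Glycosylphosphatidylinositol (GPI)-anchor biosynthesis	20	KEGG
Glycan biosynthesis and metabolism	Glycosphingolipid biosynthesis-ganglio series	1	KEGG
Glycan biosynthesis and metabolism	Other glycan degradation	1	KEGG
Lectins	*	128	KEGG
GPI-anchored proteins	Enzymes	18	KEGG
GPI-anchored proteins	Receptors	16	KEGG
GPI-anchored proteins	Antigens	67	KEGG
GPI-anchored proteins	Others	15	KEGG
Proteoglycans	Cell surface proteoglycans	12	KEGG
Proteoglycans	ECM proteoglycans	36	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	166	KEGG
Glycosaminoglycan binding proteins	Hyaluronan	18	KEGG
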