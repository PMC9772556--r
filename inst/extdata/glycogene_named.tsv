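group	family	gene_id	symbol	source
Glycosyltransferases	CSGlcA-T	316533	Chpf	CAZy
Glycosyltransferases	CSGlcA-T	296733	Chpf2	CAZy
Glycosyltransferases	Fucosyl-T	84597	Fut9	CAZy
Glycosyltransferases	GalNAc-T	304571	Galnt9	CAZy
Glycosyltransferases	GalNAc-T	288611	Galnt17	CAZy
Glycosyltransferases	GalNAc-T	64828	B4galnt1	CAZy
Glycosyltransferases	GalNAc-T	117108	B3gat1	CAZy
Glycosyltransferases	GalNAc-T	309105	B4galnt4	CAZy
Glycosyltransferases	Gal-T	362275	B4galt5	CAZy
Glycosyltransferases	GlcNAc-T	29582	Mgat3	CAZy
Glycosyltransferases	GlcNAc-T	65271	Mgat5	CAZy
Glycosyltransferases	GlcNAc-T	56819	Extl3	CAZy
Glycosyltransferases	GlcNAc-T	361368	Large1	CAZy
Glycosyltransferases	Glc-T	171129	Uggt1	CAZy
Glycosyltransferases	Man-T	362465	Tmtc1	CAZy
Glycosyltransferases	Man-T	308519	Dpy19l3	CAZy
Glycosyltransferases	Sia-T	301155	St6gal2	CAZy
Glycosyltransferases	Sia-T	364901	St8sia5	CAZy
Glycosyltransferases	Sia-T	25547	St8sia3	CAZy
Glycosyltransferases	Sia-T	363040	St3gal4	CAZy
Glycosyltransferases	Xyl-T	64133	Xylt1	CAZy
Glycosyltransferases	GT-unassigned	245960	Alg10	CAZy
Glycosyltransferases	GT-unassigned	290794	Tnks	CAZy
Glycosyltransferases	GT-unassigned	363160	Stt3b	CAZy
Glycosyltransferases	Ribosyltransferase	24465	Hprt1	CAZy
Glycosyltransferases	Ribosyltransferase	117544	Ppat	CAZy
Glycosyltransferases	GT-unassigned	290029	Pnp	CAZy
Glycoside hydrolases	Hyaluronidases	367166	Hyal1	CAZy
Glycoside hydrolases	Hyalurononglucosaminidase	308797	Cemip	CAZy
Glycoside hydrolases	Hyalurononglucosaminidase	309400	Tmem2	CAZy
Glycoside hydrolases	Lysozomal Enzymes	367562	Gaa	CAZy
Glycoside hydrolases	Lysozomal Enzymes	684536	Gba	CAZy
Glycoside hydrolases	Mannosidases	295319	Man1a2	CAZy
Glycoside hydrolases	Mannosidases	308757	Man2a2	CAZy
Glycoside hydrolases	Nucleotide Synthesis	114711	Gne	CAZy
Glycoside hydrolases	Fucosidase	292485	Fuca2	CAZy
Glycoside hydrolases	Nucleotide Synthesis	294673	Hexb	CAZy
Glycoside hydrolases	GH-unassigned	25211	Lyz2	CAZy
Glycan biosynthesis and metabolism	Glycosaminoglycan biosynthesis	9100001	Hs3st5	KEGG
Lectins	I-type	50687	L1cam	KEGG
Lectins	Calnexin/calreticulin	64202	Calr	KEGG
Lectins	C-Type	29403	Asgr2	KEGG
GPI-anchored proteins	Antigens	288280	Ncam2	KEGG
GPI-anchored proteins	Antigens	24586	Ncam1	KEGG
GPI-anchored proteins	Antigens	25356	Cntn2	KEGG
GPI-anchored proteins	Others	58920	Gpc1	KEGG
Proteoglycans	ECM proteoglycans	25592	Agrn	KEGG
Proteoglycans	Cell surface proteoglycans	56782	Srgn	KEGG
Proteoglycans	Cell surface proteoglycans	54226	App	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	29715	Slc8a1	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	65047	Slit1	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	83467	Slit3	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	687064	Col25a1	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	116683	Efna5	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	140447	Slc8a2	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	310207	Sema5a	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	29366	Serpine2	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	25352	Sod3	KEGG
Glycosaminoglycan binding proteins	Heparan sulfate/Haparin	25728	Apoe	KEGG
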