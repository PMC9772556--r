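regulation	category	subcategory	gene_id	symbol	fc
down	GTs	CSGlcA-T	316533	Chpf	-1.21
down	GTs	CSGlcA-T	296733	Chpf2	-1.5
down	GTs	Fucosyl-T	84597	Fut9	-5.51
down	GTs	GalNAc-T	304571	Galnt9	-1.51
down	GTs	GalNAc-T	288611	Galnt17	-1.37
down	GTs	GalNAc-T	64828	B4galnt1	-1.24
down	GTs	GalNAc-T	117108	B3gat1	-1.19
down	GTs	GalNAc-T	309105	B4galnt4	-1.16
down	GTs	Gal-T	362275	B4galt5	-1.22
down	GTs	GlcNAc-T	29582	Mgat3	-1.19
down	GTs	GlcNAc-T	65271	Mgat5	-1.54
down	GTs	GlcNAc-T	56819	Extl3	-1.44
down	GTs	GlcNAc-T	361368	Large1	-1.29
down	GTs	Glc-T	171129	Uggt1	-1.45
down	GTs	Man-T	362465	Tmtc1	-1.40
down	GTs	Man-T	308519	Dpy19l3	-1.40
down	GTs	Sia-T	301155	St6gal2	-1.62
down	GTs	Sia-T	364901	St8sia5	-1.36
down	GTs	Sia-T	25547	St8sia3	-1.28
down	GTs	Xyl-T	64133	Xylt1	-1.59
down	GTs	uncertain	245960	Alg10	-1.58
down	GTs	uncertain	290794	Tnks	-1.32
down	GTs	uncertain	363160	Stt3b	-1.26
down	GHs	Hyaluronidases	367166	Hyal1	-1.44
down	GHs	Hyalurononglucosaminidase	308797	Cemip	-1.51
down	GHs	Hyalurononglucosaminidase	309400	Tmem2	-1.64
down	GHs	Lysozomal Enzymes	367562	Gaa	-1.19
down	GHs	Lysozomal Enzymes	684536	Gba	-1.19
down	GHs	Mannosidases	295319	Man1a2	-1.27
down	GHs	Mannosidases	308757	Man2a2	-1.30
down	GHs	Nucleotide Synthesis	114711	Gne	-1.76
up	GTs	Ribosyltransferase	24465	Hprt1	1.20
up	GTs	Ribosyltransferase	117544	Ppat	1.35
up	GTs	Sia-T	363040	St3gal4	1.28
up	GTs	uncertain	290029	Pnp	1.36
up	GHs	Fucosidase	292485	Fuca2	1.25
up	GHs	Nucleotide Synthesis	294673	Hexb	1.20
up	GHs	uncertain	25211	Lyz2	1.39
down	Lectins	.	50687	L1cam	-1.37
down	Lectins	.	64202	Calr	-1.20
down	GPI-anchored proteins	.	288280	Ncam2	-1.58
down	GPI-anchored proteins	.	24586	Ncam1	-1.26
down	GPI-anchored proteins	.	25356	Cntn2	-1.39
down	GPI-anchored proteins	.	58920	Gpc1	-1.24
down	Proteoglycans	.	25592	Agrn	-1.51
down	Proteoglycans	.	56782	Srgn	-1.29
down	Proteoglycans	.	54226	App	-1.18
down	GAG binding proteins	.	29715	Slc8a1	-1.82
down	GAG binding proteins	.	65047	Slit1	-1.71
down	GAG binding proteins	.	83467	Slit3	-1.62
down	GAG binding proteins	.	687064	Col25a1	-1.58
down	GAG binding proteins	.	116683	Efna5	-1.51
down	GAG binding proteins	.	140447	Slc8a2	-1.29
down	GAG binding proteins	.	310207	Sema5a	-1.19
up	Lectins	.	29403	Asgr2	1.91
up	GAG binding proteins	.	29366	Serpine2	1.27
up	GAG binding proteins	.	25352	Sod3	1.26
up	GAG binding proteins	.	25728	Apoe	1.29
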