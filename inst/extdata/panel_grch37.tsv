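# Pharmacogene variant panel: 67 SNP/indel loci in 19 genes.
# Coordinates are 1-based GRCh37/hg19. ref is the allele carried by the
# star-nomenclature reference (*1) haplotype, which can differ from the
# genome reference assembly at a small number of loci (e.g. rs776746).
# aliases: comma-separated rsid synonyms resolvable on lookup; label keeps
# legacy descriptive names for non-rsid entries.
rsid	aliases	gene	chrom	pos	ref	alt	region_class	label
rs1801131	.	MTHFR	1	11854476	T	G	exonic	.
rs1801133	.	MTHFR	1	11856378	G	A	exonic	.
rs67376798	.	DPYD	1	97547947	T	A	exonic	.
rs3918290	.	DPYD	1	97915614	C	T	intronic	.
rs12248560	.	CYP2C19	10	96521657	C	T	upstream	.
rs28399504	.	CYP2C19	10	96522463	A	G	exonic	.
rs41291556	.	CYP2C19	10	96535173	T	C	exonic	.
rs17884712	.	CYP2C19	10	96535246	G	A	exonic	.
rs4986893	.	CYP2C19	10	96540410	G	A	exonic	.
rs4244285	.	CYP2C19	10	96541616	G	A	exonic	.
rs1799853	.	CYP2C9	10	96702047	C	T	exonic	.
rs9332131	.	CYP2C9	10	96731043	TA	T	exonic	.
rs1057910	.	CYP2C9	10	96741053	A	C	exonic	.
rs28371686	.	CYP2C9	10	96741058	C	G	exonic	.
rs1800497	.	ANKK1	11	113270828	G	A	exonic	.
rs1954787	.	GRIK4	11	120727296	T	C	intronic	.
rs2306283	.	SLCO1B1	12	21329738	A	G	exonic	.
rs4149056	.	SLCO1B1	12	21331549	T	C	exonic	.
rs9923231	.	VKORC1	16	31107689	C	T	upstream	.
rs2108622	.	CYP4F2	19	15990431	C	T	exonic	.
rs12979860	.	IFNL3	19	39738787	C	T	intronic	.
rs1051266	.	SLC19A1	21	46957794	G	A	exonic	.
rs4633	.	COMT	22	19950235	C	T	exonic	.
rs4818	.	COMT	22	19951207	C	G	exonic	.
rs4680	.	COMT	22	19951271	G	A	exonic	.
rs1135840	.	CYP2D6	22	42522613	C	G	exonic	.
rs765776661	.	CYP2D6	22	42522670	TGGGGGACT	T	exonic	G4125_4133 T
rs28371731	rs4987144	CYP2D6	22	42522964	C	T	exonic	.
rs72549346	.	CYP2D6	22	42523115	C	A	intronic	.
rs72549347	rs147960066	CYP2D6	22	42523210	C	T	intronic	.
rs2837172	.	CYP2D6	22	42523409	G	C	intronic	.
rs72549349	.	CYP2D6	22	42523535	A	G	exonic	.
rs5030867	.	CYP2D6	22	42523858	T	G	exonic	.
rs16947	.	CYP2D6	22	42523943	C	T	exonic	.
rs5030656	.	CYP2D6	22	42524175	GCTT	G	exonic	.
rs72549351	.	CYP2D6	22	42524213	CT	C	exonic	.
rs72549352	.	CYP2D6	22	42524230	A	G	intronic	.
rs35742686	.	CYP2D6	22	42524244	CT	C	exonic	.
rs72549353	rs758320086	CYP2D6	22	42524327	C	A	exonic	.
rs72549354	.	CYP2D6	22	42524696	G	A	exonic	.
rs72549356	rs553846709	CYP2D6	22	42524814	G	A	intronic	.
rs3892097	.	CYP2D6	22	42524947	C	T	intronic	.
rs5030865	.	CYP2D6	22	42525035	C	A	exonic	.
rs5030655	.	CYP2D6	22	42525086	AG	A	exonic	.
rs1058164	.	CYP2D6	22	42525132	G	C	exonic	.
rs61736512	.	CYP2D6	22	42525755	C	T	exonic	.
rs28371706	.	CYP2D6	22	42525772	C	T	exonic	.
rs5030863	rs201377835	CYP2D6	22	42525797	C	G	exonic	.
rs72549357	rs774671100	CYP2D6	22	42525821	GA	G	exonic	.
rs5030862	.	CYP2D6	22	42525911	G	A	exonic	.
rs1065852	.	CYP2D6	22	42526694	G	A	exonic	.
rs769258	.	CYP2D6	22	42526763	C	T	exonic	.
rs28735595	.	CYP2D6	22	42527793	T	C	upstream	.
rs1080985	.	CYP2D6	22	42528382	C	G	upstream	.
rs2228001	.	TMEM	3	14187449	A	C	exonic	.
rs2231142	.	ABCG2	4	89052323	G	T	exonic	.
rs2231137	.	ABCG2	4	89061114	C	T	exonic	.
rs1142345	.	TPMT	6	18130918	T	C	exonic	.
rs1800584	.	TPMT	6	18133890	C	T	intronic	.
rs1800460	.	TPMT	6	18139228	C	T	exonic	.
rs1800462	.	TPMT	6	18143955	C	G	exonic	.
rs1061235	.	HLA	6	29913590	A	T	exonic	HLA-A*31:01 tag
rs2395029	.	HLA	6	31431780	T	G	exonic	HLA-B*57:01 tag
rs1128503	.	ABCB1	7	87179601	A	G	exonic	.
rs2032582	.	ABCB1	7	87160618	A	C	exonic	.
rs1045642	.	ABCB1	7	87138645	A	G	exonic	.
rs776746	.	CYP3A5	7	99270539	T	C	intronic	.
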