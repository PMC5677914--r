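# Single-marker phenotype translations for genes typed by one tag SNP
# (PharmGKB-derived). pattern: hom_ref / het / hom_alt / any_alt / default,
# matched in file order, first hit wins; default rows catch everything
# else. gene_out is the gene symbol reported on the phenotype record (the
# two HLA tag SNPs report as separate HLA loci).
rsid	gene_out	pattern	phenotype_class
rs1061235	HLA-A	any_alt	carrier
rs1061235	HLA-A	default	non_carrier
rs2395029	HLA-B	any_alt	carrier
rs2395029	HLA-B	default	non_carrier
rs9923231	VKORC1	any_alt	decreased_function
rs9923231	VKORC1	default	normal_function
rs4149056	SLCO1B1	any_alt	decreased_function
rs4149056	SLCO1B1	default	normal_function
rs12979860	IFNL3	any_alt	decreased_function
rs12979860	IFNL3	default	normal_function
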