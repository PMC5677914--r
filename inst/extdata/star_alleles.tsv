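# Star-allele definition table (tag-variant form), transcribed from the
# public P450 nomenclature / CPIC allele-definition resources. Each star
# allele is defined by the minimal set of panel variants that discriminates
# it on this panel; sub-alleles sharing the same tags (e.g. *2A under *2)
# collapse to the parent name. required_allele refers to the panel's
# ref/alt strings. activity_value: per-allele functional value used by the
# activity-score system (CYP2D6) and the generic function-sum translation
# for other metabolizer genes; "unknown" when not established.
# *1 rows (reference haplotype, no defining variants) and the CYP2D6 whole
# gene deletion *5 (never called from SNP data; attached by copy-number
# integration) use "." for rsid/required_allele.
gene	star_name	rsid	required_allele	activity_value
CYP2D6	*1	.	.	1
CYP2D6	*2	rs16947	T	1
CYP2D6	*3	rs35742686	C	0
CYP2D6	*4	rs3892097	T	0
CYP2D6	*5	.	.	0
CYP2D6	*6	rs5030655	A	0
CYP2D6	*7	rs5030867	G	0
CYP2D6	*8	rs5030865	A	0
CYP2D6	*9	rs5030656	G	0.5
CYP2D6	*10	rs1065852	A	0.5
CYP2D6	*17	rs28371706	T	0.5
CYP2D6	*29	rs61736512	T	0.5
CYP2D6	*35	rs769258	T	1
CYP2C19	*1	.	.	1
CYP2C19	*2	rs4244285	A	0
CYP2C19	*3	rs4986893	A	0
CYP2C19	*4	rs28399504	G	0
CYP2C19	*8	rs41291556	C	0
CYP2C19	*9	rs17884712	A	0.5
CYP2C19	*17	rs12248560	T	1.5
CYP2C9	*1	.	.	1
CYP2C9	*2	rs1799853	T	0.5
CYP2C9	*3	rs1057910	C	0
CYP2C9	*5	rs28371686	G	0
CYP2C9	*6	rs9332131	T	0
CYP3A5	*1	.	.	1
CYP3A5	*3	rs776746	C	0
TPMT	*1	.	.	1
TPMT	*2	rs1800462	G	0
TPMT	*3A	rs1800460	T	0
TPMT	*3A	rs1142345	C	0
TPMT	*3B	rs1800460	T	0
TPMT	*3C	rs1142345	C	0
TPMT	*4	rs1800584	T	0
DPYD	*1	.	.	1
DPYD	*2A	rs3918290	T	0
DPYD	c.2846A>T	rs67376798	A	0.5
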