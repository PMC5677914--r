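# Diplotype function-score -> metabolizer phenotype translation.
# score = sum over the two haplotypes of activity_value x copy multiplicity.
# A phenotype class applies when score > min_score, or score == min_score
# with inclusive = TRUE; the class with the greatest satisfied threshold
# wins. CYP2D6 rows encode the published activity-score convention
# (0 poor; 0<s<1 intermediate; 1<=s<=2 extensive; >2 ultrarapid); other
# genes encode the corresponding CPIC diplotype translations (rapid
# CYP2C19 collapses into ultrarapid; CYP3A5 expressors score >= 1).
gene	phenotype_class	min_score	inclusive
CYP2D6	poor	0	TRUE
CYP2D6	intermediate	0	FALSE
CYP2D6	extensive	1	TRUE
CYP2D6	ultrarapid	2	FALSE
CYP2C19	poor	0	TRUE
CYP2C19	intermediate	0	FALSE
CYP2C19	extensive	2	TRUE
CYP2C19	ultrarapid	2	FALSE
CYP2C9	poor	0	TRUE
CYP2C9	intermediate	0	FALSE
CYP2C9	extensive	2	TRUE
CYP3A5	poor	0	TRUE
CYP3A5	intermediate	0	FALSE
CYP3A5	extensive	2	TRUE
TPMT	poor	0	TRUE
TPMT	intermediate	0	FALSE
TPMT	extensive	2	TRUE
DPYD	poor	0	TRUE
DPYD	intermediate	0	FALSE
DPYD	extensive	2	TRUE
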