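compound	target	predictors	metric	sensitive_cmp	sensitive_value	resistant_cmp	resistant_value
PLX4720	BRAF	BRAF	ActArea	>=	2.05	<=	0.47
AZD6244	MEK	BRAF	ActArea	>=	3.02	<=	0.69
Erlotinib	EGFR	EGFR,KRAS	ActArea	>=	1.74	<=	0.42
Nutlin-3	MDM2	TP53	IC50	<=	4.26	>=	6.94
BYL719	PIK3CA	PIK3CA,PTEN	EC50	<=	3.04	>	3.04
BYL719	PIK3CA	PIK3CA,PTEN	Amax	<=	-30	>	-30
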