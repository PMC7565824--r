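protein1	protein2	experimental	combined_score
NF1	SDC2	900	900
NF1	VCP	900	900
NF1	KRAS	950	950
KRAS	RAF1	950	950
KRAS	BRAF	950	950
KRAS	EGFR	900	900
KRAS	PIK3CA	900	900
PIK3CA	AKT1	950	950
PIK3CA	RAC1	900	900
PIK3CA	PTEN	900	900
EGFR	SMARCA4	800	800
RAC1	PAK1	900	900
PAK1	LIMK1	900	900
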