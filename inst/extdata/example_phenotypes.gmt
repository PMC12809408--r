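SASP	illustrative senescence-associated secretory phenotype factors	IL6	IL1A	IL1B	CXCL8	CCL2	CCL5	MMP1	MMP3	MMP12	SERPINE1	IGFBP3	TNF
NFKB_ACTIVATION	illustrative NF-kB pathway activation targets	NFKB1	NFKB2	RELA	RELB	NFKBIA	TNFAIP3	BIRC3	ICAM1	VCAM1	CXCL1	CXCL2
CELL_CYCLE_ARREST	illustrative senescence growth-arrest markers	CDKN1A	CDKN2A	CDKN2B	CDKN1C	TP53	RB1	E2F7	GADD45A
PROTEOSTASIS_LOSS	illustrative proteostasis/chaperone decline markers	HSPA1A	HSPA1B	HSPB1	DNAJB1	HSP90AA1	SQSTM1	LAMP2	CTSD	PSMB5
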