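EDC_QC	Epidermal differentiation complex genes used for the sample QC signal criterion	FLG	FLG2	LORICRIN	LCE1A	S100A7	S100A8	SPRR2E	SPRR1B	IVL
MT_NORM	Mitochondrially encoded genes used as the reference set for ratio normalization	MT-ATP6	MT-ATP8	MT-CO1	MT-CO2	MT-CO3	MT-CYB	MT-ND2	MT-ND3	MT-ND4	MT-ND4L	MT-ND5	MT-ND6
KRTAP	Keratin-associated protein genes used as a hair-contamination signature	KRTAP1-1	KRTAP1-3	KRTAP1-5	KRTAP2-3	KRTAP3-1	KRTAP3-2	KRTAP4-9	KRTAP9-2	KRTAP10-12	KRTAP11-1
LAYER_CORNEUM	Stratum corneum marker genes (outermost epidermal layer)	LCE3A	S100B	CDSN	KPRP	LELP1
LAYER_GRANULOSUM	Stratum granulosum marker genes	TGM3	KRT2	DSC1	CALML5	GRHL1
LAYER_SPINOSUM	Stratum spinosum marker genes	KRT1	KRT10	DSP	DSC3	PERP
LAYER_BASALE	Stratum basale marker genes (innermost epidermal layer)	KRT5	KRT14	KRT15	TP63	COL17A1
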