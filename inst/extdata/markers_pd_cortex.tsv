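cell_type	probeset_id	gene_symbol
neuron	221805_at	NEFL
neuron	221801_x_at	NEFL
neuron	221916_at	NEFL
neuron	201313_at	ENO2
neuron	210040_at	SLC12A5
neuron	205737_at	KCNQ2
astrocyte	203540_at	GFAP
astrocyte	210068_s_at	AQP4
astrocyte	210906_x_at	AQP4
astrocyte	201667_at	GJA1
oligodendrocyte	211836_s_at	MOG
oligodendrocyte	214650_x_at	MOG
oligodendrocyte	216617_s_at	MAG
oligodendrocyte	207323_s_at	MBP
oligodendrocyte	209072_at	MBP
microglia	215051_x_at	AIF1
microglia	209901_x_at	AIF1
microglia	213095_x_at	AIF1
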