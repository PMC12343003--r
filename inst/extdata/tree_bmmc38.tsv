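# Curated 38-cell-type bone-marrow hierarchy.
# node <name> <population> <lineage_class>; edge <parent> <child> <kind>.
# Solid edges: continuous intramedullary differentiation; dashed edges:
# mature cells recruited from outside the bone marrow.
node	HSC/MPP	HSPCs	HSPC
node	LMPP	HSPCs	HSPC
node	CLP	HSPCs	HSPC
node	CMP	HSPCs	HSPC
node	MDP	HSPCs	HSPC
node	GMP	HSPCs	HSPC
node	CDP	HSPCs	HSPC
node	MEP	HSPCs	HSPC
node	MKP	HSPCs	HSPC
node	GMP-Mono	Monocytes	myeloid
node	CD14 Mono	Monocytes	myeloid
node	CD16 Mono	Monocytes	myeloid
node	mo-DC	DCs	myeloid
node	pre-DC	DCs	myeloid
node	pDC	DCs	myeloid
node	cDC1	DCs	myeloid
node	MK	Erythrocytes	myeloid
node	pro-Ery1	Erythrocytes	myeloid
node	pro-Ery2	Erythrocytes	myeloid
node	Ery	Erythrocytes	myeloid
node	pre-pro-B	B cells	B
node	Early-pro-B	B cells	B
node	Late-pro-B	B cells	B
node	pre-B	B cells	B
node	Immature B	B cells	B
node	Naive B	B cells	B
node	Memory B 1	B cells	B
node	Memory B 2	B cells	B
node	CD8 Tnaive	CD8 T cells	TNK
node	CD8 Tdpe	CD8 T cells	TNK
node	CD8 Tmpe	CD8 T cells	TNK
node	CD8 Teff	CD8 T cells	TNK
node	CD8 Tex	CD8 T cells	TNK
node	CD4 Tnaive	CD4 T cells	TNK
node	CD4 Tem	CD4 T cells	TNK
node	CD4 Treg	CD4 T cells	TNK
node	NK	NK cells	TNK
node	NK-XCL1	NK cells	TNK
edge	HSC/MPP	LMPP	solid
edge	HSC/MPP	CMP	solid
edge	LMPP	CLP	solid
edge	CMP	GMP	solid
edge	CMP	MEP	solid
edge	CMP	MDP	solid
edge	GMP	GMP-Mono	solid
edge	GMP-Mono	CD14 Mono	solid
edge	CD14 Mono	CD16 Mono	solid
edge	CD14 Mono	mo-DC	solid
edge	MDP	CDP	solid
edge	CDP	pre-DC	solid
edge	pre-DC	pDC	solid
edge	pre-DC	cDC1	solid
edge	MEP	MKP	solid
edge	MKP	MK	solid
edge	MEP	pro-Ery1	solid
edge	pro-Ery1	pro-Ery2	solid
edge	pro-Ery2	Ery	solid
edge	CLP	pre-pro-B	solid
edge	pre-pro-B	Early-pro-B	solid
edge	Early-pro-B	Late-pro-B	solid
edge	Late-pro-B	pre-B	solid
edge	pre-B	Immature B	solid
edge	Immature B	Naive B	solid
edge	Naive B	Memory B 1	dashed
edge	Naive B	Memory B 2	dashed
edge	CLP	CD8 Tnaive	dashed
edge	CD8 Tnaive	CD8 Tdpe	dashed
edge	CD8 Tnaive	CD8 Tmpe	dashed
edge	CD8 Tmpe	CD8 Teff	dashed
edge	CD8 Teff	CD8 Tex	dashed
edge	CLP	CD4 Tnaive	dashed
edge	CD4 Tnaive	CD4 Tem	dashed
edge	CD4 Tnaive	CD4 Treg	dashed
edge	CLP	NK	dashed
edge	NK	NK-XCL1	dashed
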