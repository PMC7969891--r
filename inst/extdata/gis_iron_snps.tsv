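chrom	rsid	pos	gene	effect_allele	other_allele	eaf	trait	beta	se
6	rs1799945	26091179	HFE	C	G	0.85	iron	-0.19	0.01
6	rs1799945	26091179	HFE	C	G	0.85	ferritin	-0.07	0.01
6	rs1799945	26091179	HFE	C	G	0.85	transferrin_saturation	-0.23	0.01
6	rs1799945	26091179	HFE	C	G	0.85	transferrin	0.11	0.01
6	rs1800562	26093141	HFE	A	G	0.07	iron	0.33	0.02
6	rs1800562	26093141	HFE	A	G	0.07	ferritin	0.20	0.02
6	rs1800562	26093141	HFE	A	G	0.07	transferrin_saturation	0.58	0.02
6	rs1800562	26093141	HFE	A	G	0.07	transferrin	-0.48	0.02
22	rs855791	37462936	TMPRSS6	A	G	0.45	iron	-0.18	0.01
22	rs855791	37462936	TMPRSS6	A	G	0.45	ferritin	-0.06	0.01
22	rs855791	37462936	TMPRSS6	A	G	0.45	transferrin_saturation	-0.19	0.01
22	rs855791	37462936	TMPRSS6	A	G	0.45	transferrin	0.04	0.01
3	rs8177240	133477701	TF	T	G	0.67	iron	-0.07	0.01
3	rs8177240	133477701	TF	T	G	0.67	transferrin_saturation	0.10	0.01
3	rs8177240	133477701	TF	T	G	0.67	transferrin	-0.38	0.01
7	rs7385804	100235970	TFR2	A	C	0.62	iron	0.06	0.01
7	rs7385804	100235970	TFR2	A	C	0.62	transferrin_saturation	0.05	0.01
9	rs651007	136153875	ABO	T	C	0.20	ferritin	-0.05	0.01
17	rs411988	56709034	TEX14	A	G	0.46	ferritin	-0.04	0.01
2	rs744653	190378750	WDR75-SLC40A1	T	C	0.85	ferritin	-0.09	0.01
2	rs744653	190378750	WDR75-SLC40A1	T	C	0.85	transferrin	0.07	0.01
3	rs9990333	195827205	TFRC	T	C	0.46	transferrin	0.06	0.01
8	rs4921915	18272466	NAT2	A	G	0.78	transferrin	0.08	0.01
11	rs6486121	13355770	ARNTL	T	C	0.63	transferrin	-0.05	0.01
11	rs174577	61604814	FADS2	A	C	0.33	transferrin	0.06	0.01
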