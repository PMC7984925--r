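no	component	rt_min	ion_mode	mz	herbs	compound_class
1	Catalpol	5.06	[M + HCOO]−	407.10	RR	Glycosides
2	Aucubin	8.40	[M + HCOO]−	391.10	RR	Glycosides
3	Gallic acid	8.58	[M − H]−	169.10	RR, RRER	Organic acid
4	Rhmannioside D	9.67	[M + HCOO]−	731.10	RR	Glycosides
5	Leonuride	14.18	[M + HCOO]−	393.10	RR	Glycosides
6	Hydroxysafflor yellow A	18.12	[M − H]−	611.10	CF	Flavonoids
7	Amygdalin	18.78	[M + HCOO]−	502.10	PS	Glycosides
8	Echinacoside	19.87	[M − H]−	785.15	RR	Glycosides
9	Calycosin-7-O-β-D-glucoside	22.24	[M + H]+	447.05	AR	Flavonoids
10	Acteoside	22.53	[M − H]−	623.15	RR	Glycosides
11	Ononin	26.59	[M + HCOO]−	475.05	AR	Glycosides
12	Calycosin	29.34	[M + H]+	285.10	AR	Flavonoids
13	Astragaloside IV	31.77	[M + HCOO]−	829.35	AR	Saponins
14	Astragaloside III	32.35	[M + HCOO]−	829.35	AR	Saponins
15	Ophiopojaponin C	33.19	[M + HCOO]−	931.35	OR	Saponins
16	Astragaloside II	33.93	[M + HCOO]−	871.40	AR	Saponins
17	Formononetin	34.99	[M + H]+	269.10	AR	Flavonoids
18	Isoastragaloside II	35.25	[M + HCOO]−	871.40	AR	Saponins
19	Rhein	37.61	[M − H]−	283.05	RRER	Anthraquinones
20	Astragaloside I	38.12	[M + HCOO]−	913.35	AR	Saponins
21	Isoastragaloside I	39.33	[M + HCOO]−	913.35	AR	Saponins
22	Emodin	43.27	[M − H]−	269.05	RRER	Anthraquinones
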