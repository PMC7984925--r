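pathway_id	description	p_value	target_gene_count
hsa04151	PI3K-Akt signaling pathway	3.19e-06	17
hsa04010	MAPK signaling pathway	1.12e-06	16
hsa04933	AGE-RAGE signaling pathway	1.04e-11	15
hsa04015	Rap1 signaling pathway	1.06e-05	13
hsa04915	Estrogen signaling pathway	6.86e-07	12
hsa04014	Ras signaling pathway	1.36e-04	12
hsa04625	C-type lectin receptor signaling pathway	2.84e-07	11
hsa04066	HIF-1 signaling pathway	4.59e-07	10
hsa04926	Relaxin signaling pathway	2.49e-06	11
hsa04068	FoxO signaling pathway	2.90e-06	11
hsa04022	cGMP-PKG signaling pathway	2.97e-06	10
hsa04668	TNF signaling pathway	4.83e-06	10
hsa04152	AMPK signaling pathway	8.98e-06	10
hsa04910	Insulin signaling pathway	2.88e-05	10
hsa04072	Phospholipase D signaling pathway	5.60e-05	10
hsa04150	mTOR signaling pathway	7.42e-05	10
hsa04920	Adipocytokine signaling pathway	6.00e-07	9
hsa04211	Longevity regulating pathway	5.27e-06	9
hsa04657	IL-17 signaling pathway	8.30e-06	9
hsa04620	Toll-like receptor signaling pathway	1.90e-05	9
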