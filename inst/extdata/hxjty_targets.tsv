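component	degree	target_genes
Catalpol	1	LGALS3
Aucubin	1	LGALS3
Gallic acid	27	CA1, TTR, IGF1R, SERPINE1, COMT, ALB, KDR, CNR2, ESR1, PARP1, FASN, ELANE, ADRA2A, ADRA2C, ADRA2B、ADRB2、DRD3、PTPN1、PTGS2, EGFR, DPP4, CNR1, FTO, OPRM1, PTGS1, RXRG, RXRA
Rhmannioside D	17	CA1, FGF2, HRAS, FN1, F2, F7, SIRT1, AKR1B1, PTPN1, SLC5A2, ACE, SELP, MMP2, MMP12, STAT3, PRKCD, RORC
Leonuride	1	SLCO1B3
Hydroxysafflor yellow A	24	CA1, PTPN1, SLC6A4, PTGS2, PRKCD, TERT, IKBKB, GSTM1, ACP1, PTPN2, GSK3B, AKR1B1, ABCB1, MMP2, MMP12, HSD11B1, APP, CNR1, MTOR, HMGCR, TLR9, F2, F10, IL1B
Amygdalin	1	LGALS3
Echinacoside	2	ALDH2, LGALS3
Calycosin-7-O-β-D-glucoside	31	TNF, ALDH2, AKR1B1, CA1, XDH, HRAS, MAPK14, F10, ADRA2C, PARP1, ABCB1, HCAR2, PTGS1, ADRA2A, EGFR, CD38, MIF, MMP9, MMP2, MMP8, ALB, MMP12, PTPN22, TLR9, PPARA, APP、LGALS3, IRAK4, SLC5A2, CASP1, INSR
Acteoside	0
Ononin	3	ALDH2, MTTP, SHBG
Calycosin	27	ABCB1, MIF, PPARA, ESR1, TLR9, EGFR, PTGS1, ALDH2, XDH, CA1, PTPN1, PON1, PLAT, F10, TNF, IGFBP3, AKR1B1, SNCA, GCGR, ADRB2, KDM1A, TNNC1, TNNT2, TNNI3, IGFBP5, IGFBP2, PPARG
Astragaloside IV	31	VEGFA, FGF1, FGF2, HPSE, LGALS3, ADRA2A, ABCB1, ADRA2C, ADRA2B, STAT3, AKT2, AKT1, CNR1, CNR2, FAAH, ADRB2, MTOR, PIK3CG, RORC, F10, IGF2R, DRD3、F7, VDR, PIK3CA, PIK3R1, PTPN2, EGFR, MMP1, SLC6A4, SELP
Astragaloside III	26	VEGFA, FGF1, FGF2, HPSE, LGALS3, RORC, ADRA2A, ADRA2C, ADRA2B, DRD3、STAT3、VDR, SLC5A1, CNR1, CNR2、HSD11B2、HSD11B1, ABCB1, ADRB2, MMP2, MMP12, IGF2R, GLB1, PPARG, ADRB3, IGF1R
Ophiopojaponin C	28	STAT3, F2, HSD11B2, HSD11B1, PTPN1, ADRB2, MMP2, MMP8, SLC5A2, SLC5A1, AKR1B1, ADRA2A, ADRA2C, ADRA2B, OPRM1, IGF1R, CASP1, DGAT1, EPHX2, LIPC, KCNH2, PRKCD, NR3C1, MMP1, FAAH, ABCG2, DPP4, ADRB3
Astragaloside II	31	VEGFA, FGF1, FGF2, HPSE, ABCB1, ADRA2A, ADRA2C, ADRA2B, STAT3, LGALS3, VDR, RORC, REN, IKBKB, ADRB2, SLC5A1, CNR1, CNR2, DRD3, EGFR, FAAH, IGF1R, IGF2R, AKT2, AKT1, INSR, FKBP5, LIPC, MMP1, TLR9, MTOR
Formononetin	4	ESR1, MTTP, AKT1, SHBG
Isoastragaloside II	32	VEGFA, FGF1, FGF2, HPSE, ABCB1, ADRA2A, ADRA2C, ADRA2B, STAT3, LGALS3, VDR, RORC, REN, IKBKB, ADRB2, SLC5A1, CNR1, CNR2, DRD3, EGFR, FAAH, IGF1R, IGF2R, AKT2, AKT1, INSR, FKBP5, LIPC, MMP1, TLR9, MTOR, SLCO1B3
Rhein	11	ALOX5, MAPK8IP1, CYP1A2, CYP2C9, CYP3A4, CYP3A43, CYP3A5, GSTP1, NR1H2, PTGS1, PTGS2
Astragaloside I	27	VEGFA, FGF1, FGF2, RORC, ADRA2A, ADRA2C, ADRA2B, VDR, LGALS3, MTOR, HPSE, MAPK14, HLA-A, P2RY12, SLC5A1, REN, ABCB1, DRD3, LIPC, MMP9, MMP8, IKBKB, PPARG, F7, CTSD, MMP3, MMP1
Isoastragaloside I	28	VEGFA, FGF1, FGF2, HPSE, ADRA2C, ADRA2B, ABCB1, VDR, LGALS3, DRD3, RORC, ADRA2A, CNR1, CNR2, SLC5A1, HLA-A, LIPC, TERT, ALDH2, PRKCD, EDNRB, IGF1R, DPP4, REN, MTOR, MMP9, MMP8, AKT1
Emodin	8	ALOX5, CYP1A2, CYP2C9, CYP3A4, CYP3A43, CYP3A5, GSTP1, NR1H2
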