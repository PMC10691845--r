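ligand	receptor	pathway	ligand_type	receptor_type
Nampt	Insr	VISFATIN	mesenchymal	trophoblast
Nrg1	Erbb4	NRG	mesenchymal	trophoblast
Ptn	Ptprz1	PTN	decidual_stroma	endothelial
Mdk	Ncl	MK	decidual_stroma	trophoblast
Vegfa	Kdr	VEGF	trophoblast	endothelial
Pdgfb	Pdgfrl	PDGF	endothelial	pericyte
Igf1	Igf1r	IGF	decidual_stroma	pericyte
Angpt1	Tek	ANGPT	decidual_stroma	endothelial
Ccl2	Ccr2	CCL	decidual_stroma	immune
Cxcl12	Cxcr4	CXCL	mesenchymal	immune
Tgfb1	Tgfbr1	TGFb	immune	trophoblast
Wnt5a	Fzd5	WNT	decidual_stroma	trophoblast
Dll4	Notch1	NOTCH	endothelial	trophoblast
Hbegf	Egfr	EGF	trophoblast	decidual_stroma
Fgf2	Fgfr2	FGF	mesenchymal	endothelial
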