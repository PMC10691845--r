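panel	role	gene
decidual_stroma	major	Prl8a2
decidual_stroma	major	Hand2
decidual_stroma	major	Bmp2
decidual_stroma	major	Wnt4
decidual_stroma	major	Pgr
decidual_stroma	major	Dkk1
decidual_stroma	major	Cryab
decidual_stroma	major	Gja1
decidual_stroma	major	Sfrp4
decidual_stroma	major	Scara5
trophoblast	major	Krt7
trophoblast	major	Krt8
trophoblast	major	Gata3
trophoblast	major	Tfap2c
trophoblast	major	Dusp9
trophoblast	major	Tfap2a
trophoblast	major	Krt18
trophoblast	major	Ovol2
trophoblast	major	Perp
trophoblast	major	Slc7a5
immune	major	Ptprc
immune	major	Cd52
immune	major	Laptm5
immune	major	Csf1r
immune	major	Cd68
immune	major	Cd3e
immune	major	Lyz2
immune	major	Cd14
immune	major	Itgam
immune	major	Cx3cr1
erythrocyte	major	Hba-a1
erythrocyte	major	Hbb-bs
erythrocyte	major	Alas2
erythrocyte	major	Gypa
erythrocyte	major	Slc4a1
erythrocyte	major	Hbb-bt
erythrocyte	major	Hba-a2
erythrocyte	major	Klf1
erythrocyte	major	Epor
erythrocyte	major	Ermap
endothelial	major	Pecam1
endothelial	major	Cdh5
endothelial	major	Cd34
endothelial	major	Egfl7
endothelial	major	Flt1
endothelial	major	Cldn5
endothelial	major	Esam
endothelial	major	Emcn
endothelial	major	Sox17
endothelial	major	Ptprb
pericyte	major	Acta2
pericyte	major	Pdgfrb
pericyte	major	Rgs5
pericyte	major	Myh11
pericyte	major	Cspg4
pericyte	major	Des
pericyte	major	Tagln
pericyte	major	Notch3
pericyte	major	Anpep
pericyte	major	Mcam
mesenchymal	major	Col1a1
mesenchymal	major	Col3a1
mesenchymal	major	Pdgfra
mesenchymal	major	Postn
mesenchymal	major	Dcn
mesenchymal	major	Fn1
mesenchymal	major	Twist1
mesenchymal	major	Prrx1
mesenchymal	major	Lum
mesenchymal	major	Fbln2
S-TGC	subtype	Nos1ap
S-TGC	subtype	Ctsq
S-TGC	subtype	Slco2a1
S-TGC	subtype	Cd44
S-TGC	subtype	Ctsj
S-TGC	subtype	Pla2g4d
P-TGC	subtype	Prl3d1
P-TGC	subtype	Prl2c2
P-TGC	subtype	Hand1
P-TGC	subtype	Cts7
P-TGC	subtype	Prl3b1
P-TGC	subtype	Prl2a1
SpT	subtype	Tpbpa
SpT	subtype	Prl8a8
SpT	subtype	Psg17
SpT	subtype	Ncam1
SpT	subtype	Prl8a6
SpT	subtype	Psg19
GlyT	subtype	Gjb3
GlyT	subtype	Pcdh12
GlyT	subtype	Gys1
GlyT	subtype	Slc5a11
GlyT	subtype	Pygl
GlyT	subtype	Gbe1
SynTI	subtype	Syna
SynTI	subtype	Ly6e
SynTI	subtype	Slc16a1
SynTI	subtype	Stra6
SynTI	subtype	Glis1
SynTI	subtype	Podxl
SynTII	subtype	Synb
SynTII	subtype	Gcm1
SynTII	subtype	Slc16a3
SynTII	subtype	Cebpa
SynTII	subtype	Vgll3
SynTII	subtype	Slc1a5
LaTP2	subtype	Epcam
LaTP2	subtype	Met
LaTP2	subtype	Lgr5
LaTP2	subtype	Sox9
LaTP2	subtype	Tead4
LaTP2	subtype	Itga6
LaTP1	subtype	Mki67
LaTP1	subtype	Top2a
LaTP1	subtype	Ccnb1
LaTP1	subtype	Cdk1
LaTP1	subtype	Ccna2
LaTP1	subtype	Bub1
JZP1	subtype	Ascl2
JZP1	subtype	Grhl1
JZP1	subtype	Tfeb
JZP1	subtype	Dlx3
JZP1	subtype	Wnt7b
JZP1	subtype	Igfbp2
JZP2	subtype	Prdm1
JZP2	subtype	Cited1
JZP2	subtype	Lifr
JZP2	subtype	Ncoa6
JZP2	subtype	Gata2
JZP2	subtype	Msx2
ChorTB	subtype	Esrrb
ChorTB	subtype	Eomes
ChorTB	subtype	Elf5
ChorTB	subtype	Cdx2
ChorTB	subtype	Bmp4
ChorTB	subtype	Id2
ProlifTB	subtype	Pcna
ProlifTB	subtype	Mcm3
ProlifTB	subtype	Mcm5
ProlifTB	subtype	Rrm2
ProlifTB	subtype	Ccne1
ProlifTB	subtype	E2f1
noncanonical	imprint_noncanonical	Sfmbt2
noncanonical	imprint_noncanonical	Gab1
noncanonical	imprint_noncanonical	Slc38a4
noncanonical	imprint_noncanonical	Smoc1
noncanonical	imprint_noncanonical	Jade1
noncanonical	imprint_noncanonical	Platr20
canonical	imprint_canonical	H19
canonical	imprint_canonical	Igf2
canonical	imprint_canonical	Snrpn
canonical	imprint_canonical	Peg3
canonical	imprint_canonical	Mest
canonical	imprint_canonical	Plagl1
canonical	imprint_canonical	Grb10
canonical	imprint_canonical	Kcnq1ot1
canonical	imprint_canonical	Dlk1
canonical	imprint_canonical	Meg3
chromatin	chromatin	Ehmt1
chromatin	chromatin	Ezh2
chromatin	chromatin	Setd5
chromatin	chromatin	Ino80
chromatin	chromatin	Dnmt3b
chromatin	chromatin	Kdm6b
chromatin	chromatin	Suz12
chromatin	chromatin	Eed
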