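DAM	disease-associated microglia markers	Lpl	Cst7	Axl	Itgax	Spp1	Cd9	Ccl6	Csf1
DAA	disease-associated astrocyte markers	Ggta1	Gsn	Osmr	Vim	Serpina3n	Ctsb	Gfap
MicroglialPanel	homeostatic plus reactive microglial panel	Hexb	Cst3	Cx3cr1	Ctsd	Csf1r	Ctss	Sparc	Tmsb4x	P2ry12	C1qa	C1qb	Tmem119	Tyrobp	Ctsb	Apoe	B2m	Fth1	Lyz2	Trem2	Axl	Cst7	Ctsl	Lpl	Cd9	Csf1	Ccl6	Itgax	Timp2
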