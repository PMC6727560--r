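# Sex-biased transcription factors and epigenetic/remodelling enzymes
# across cardiac development, transcribed from the published tables of
# bias calls (female- and male-biased factors; 60 and 61 rows).
# Codes: XX female-biased, XY male-biased, nb expressed but not biased,
# empty cell = expression not detected. Stages: ES cells, derived
# cardiac precursors (CP), embryonic hearts at 8.5/9.5/10.5 dpc,
# neonatal (p1) and adult hearts.
# Transcription notes: the source rendering preserves each row's code
# sequence but stage-column placement was reconstructed from the table
# group ordering and every explicit per-gene statement in the text;
# within-group placements without such a statement are judgment calls.
# Two internally inconsistent artifact rows of the source text (Spic,
# Hmgb1) were dropped to match the printed row totals. The Aff3 row's
# chromosome cell did not survive extraction; set to 1.
gene	ES	CP	8.5	9.5	10.5	p1	Adult	Chr	table	reg_class
Hmgb3	XX							X	female	TF
Dmrtb1	XX							4	female	TF
Hoxb9	XX							11	female	TF
Hoxc8	XX							15	female	TF
Klf8	XX							X	female	TF
Mitf	XX							6	female	TF
Prdm14	XX							1	female	TF
Rhox1	XX							X	female	TF
Sohlh2	XX							3	female	TF
Tbx15	XX							3	female	TF
Zeb1	XX							18	female	TF
Zfp182	XX							X	female	TF
Zfp275	XX							X	female	TF
Zfp449	XX							X	female	TF
Zfp59	XX							7	female	TF
Zxdb	XX							X	female	TF
Mecp2	XX							X	female	ERE
Nkap	XX							X	female	TF
Ogt	XX							X	female	ERE
Top2b	XX							14	female	ERE
Trim16	XX							11	female	ERE
Zmym3	XX							X	female	ERE
Apobec2	XX							17	female	ERE
Baz2b	XX							2	female	ERE
Prrx1	XX						XX	1	female	TF
Kdm6a	XX	XX	XX	XX	XX	XX	XX	X	female	ERE
Lbh	XX						XX	17	female	TF
Meis2	XX						XY	2	female	TF
Zfp9	XX						XY	6	female	TF
Aff2	XX	XX					nb	X	female	TF
Atrx	XX		XY				nb	X	female	ERE
Arid1b	nb			XX	XX		nb	17	female	ERE
Bhlhe40	nb			XX			XX	6	female	TF
Zfp51	nb			XX	XX			17	female	TF
Klf15	nb			XX				6	female	TF
Mafk	nb			XX	XX			5	female	TF
Aff3	nb			XX	XX	XX	XY	1	female	TF
Heyl							XX	4	female	TF
Hopx							XX	5	female	TF
Dlx1							XX	2	female	TF
Rsl1							XX	13	female	TF
Zbtb45							XX	7	female	TF
Zfp282							XX	6	female	TF
Zfp472							XX	17	female	TF
Zfp498							XX	5	female	TF
Zfp758							XX	17	female	TF
Zkscan14							XX	5	female	TF
Zkscan6							XX	11	female	TF
Nat10							XX	2	female	ERE
Senp3							XX	11	female	ERE
Setmar							XX	6	female	ERE
Sirt7							XX	11	female	ERE
Suv39h2							XX	2	female	ERE
Bard1							XX	1	female	ERE
Cbx2							XX	11	female	ERE
Cbx7							XX	15	female	ERE
Rcc1							XX	4	female	ERE
Irf4							XX	13	female	TF
Cecr2							XX	6	female	ERE
Nkx2-5						XX	XX	17	female	TF
Egr4	XY							6	male	TF
Cdx1	XY							18	male	TF
E2f7	XY							10	male	TF
Eomes	XY							9	male	TF
Evx1	XY							6	male	TF
Foxi3	XY							6	male	TF
Foxp4	XY							17	male	TF
Insm1	XY							2	male	TF
Lin28a	XY							4	male	TF
Mesp1	XY							7	male	TF
Mixl1	XY							1	male	TF
Nr6a1	XY							2	male	TF
Pou2f3	XY							9	male	TF
Sox11	XY							12	male	TF
Sp5	XY							9	male	TF
Sp8	XY							12	male	TF
T	XY							17	male	TF
Tcf7	XY							11	male	TF
Wiz	XY							17	male	TF
Ybx2	XY							11	male	TF
Zglp1	XY							9	male	TF
Dnmt3b	XY							2	male	ERE
Dnmt3l	XY							10	male	ERE
Phc1	XY							6	male	ERE
Plac8	XY							5	male	ERE
Tdrd5	XY							1	male	ERE
Bahcc1	XY							11	male	ERE
Kdm6c	XY	XY	XY		XY	XY	XY	Y	male	ERE
Bcl6b	XY		XY				nb	11	male	TF
Irf8	XY		XY				nb	8	male	TF
Arid1a	XY						XY	4	male	ERE
Lef1	XY		XY			XY	XY	3	male	TF
Tbx20	XY	XY			XY	XY		9	male	TF
Smarcd1	XY						XY	15	male	ERE
Zbtb7a	XY						XY	10	male	TF
Hif3a	XY					XY	XY	7	male	TF
Nfkb2	XY					XY	XY	19	male	TF
Pbx2	XY	XY					nb	17	male	TF
Prdm6	XY						XY	18	male	ERE
Id2	XY						XY	12	male	TF
Dot1l	XY	XY					XX	10	male	ERE
Zfp296	XY						XX	7	male	TF
Gata4	XY						nb	14	male	TF
Mycn	XY						nb	12	male	TF
Hdac5	XY						nb	11	male	ERE
Nfxl1	XY						nb	5	male	TF
Pax6	nb		XY					2	male	TF
Brd4	nb		XY				nb	17	male	ERE
Carhsp1	nb		XY	XY	XY			16	male	TF
Csde1	nb		XY	XY		nb	nb	3	male	TF
Mef2d	nb		XY					3	male	TF
Atf5	nb						XY	7	male	TF
Bach2	nb						XY	4	male	TF
Cdc5l	nb						XY	17	male	TF
Crebzf	nb						XY	7	male	TF
Gm13139	nb						XY	4	male	TF
Hmgb2	nb						XY	8	male	TF
Klf10	nb						XY	15	male	TF
Nfic	nb						XY	10	male	TF
Nfkb1	nb						XY	3	male	TF
Pias2	nb						XY	18	male	ERE
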