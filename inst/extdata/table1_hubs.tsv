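hub	n_interfaces	domains	functional_group	table1_class
Boi2	2	SH3_1,SAM_2,PH	Bud Formation	Static
Cdc42	2	Ras	Bud Formation	Static
Cla4	2	PH, PDB(CRIB), Pkinase	Bud Formation	Dynamic
Cdc28	2	Pkinase	Cyclin Proteins	Static
Clb1	2	Cyclin_N, Cyclin_C	Cyclin Proteins	Dynamic
Clb2	2	Cyclin_N, Cyclin_C	Cyclin Proteins	Dynamic
Clb3	2	Cyclin_N, Cyclin_C	Cyclin Proteins	Dynamic
Clb4	2	Cyclin_N, Cyclin_C	Cyclin Proteins	Dynamic
Clb5	2	Cyclin_N, Cyclin_C	Cyclin Proteins	Dynamic
Clb6	2	Cyclin_N, Cyclin_C	Cyclin Proteins	Dynamic
Cln1	2	Cyclin_N	Cyclin Proteins	Dynamic
Cln2	2	Cyclin_N	Cyclin Proteins	Dynamic
Cln3	2	Cyclin_N	Cyclin Proteins	Dynamic
Pho85	2	Pkinase	Cyclin Proteins	Static
Yta7	1	AAA, bromodomain	Cyclin Proteins	Static
Act1	2	Actin	Structural	Static
Mlc1	2	-	Structural	Static
Gdi1	1	GDI	Protein Sorting/Transport	Static
Mrs6	2	GDI	Protein Sorting/Transport	Static
Vps21	2	Ras	Protein Sorting/Transport	Static
Ykt6	2	Longin, Synaptobrevin	Protein Sorting/Transport	-
Ypt52	2	Ras	Protein Sorting/Transport	Static
Gsp1	2	Ras	Others	-
Hsc82	2	HATPase_c, HSP90	Others	-
Hsp82	2	HATpase_c, HSP90	Others	-
Mtr3	1	RNase_PH	Others	-
Ras2	2	Ras	Others	-
Sgn1	1	RRM_1	Others	-
Slt2	2	Pkinase	Others	-
Snf1	2	Pkinase, UBA_2	Others	-
Dbp8	1	DEAD, Helicase_c	Ribosomal RNA Processing	-
Dbp9	1	DEAD, Helicase_c	Ribosomal RNA Processing	-
Drs1	2	DEAD, Helicase_c	Ribosomal RNA Processing	-
Has1	1	DEAD, Helicase_c, DUF4217	Ribosomal RNA Processing	-
Hca4	1	DEAD, Helicase_c, DUF4217	Ribosomal RNA Processing	-
Spb4	1	DEAD, Helicase_c, DUF4217	Ribosomal RNA Processing	-
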