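Hugo_Symbol	Tumor_Sample_Barcode	Variant_Classification	Protein_position	t_alt_count	t_ref_count	oncogenic
KRAS	TCGA-SYN-0035	Missense_Mutation	452	23	52	FALSE
TCF7L2	TCGA-SYN-0005	Deletion	267	91	192	FALSE
TP53	TCGA-SYN-0018	Nonsense_Mutation	180	11	93	TRUE
TCF7L2	TCGA-SYN-0017	Nonsense_Mutation	196	12	107	TRUE
SOX9	TCGA-SYN-0033	Frame_Shift_Ins	24	35	59	TRUE
KRAS	TCGA-SYN-0026	Splice_Site	201	114	187	TRUE
SOX9	TCGA-SYN-0009	Missense_Mutation	195	20	52	TRUE
TP53	TCGA-SYN-0017	Frame_Shift_Del	328	97	70	TRUE
SOX9	TCGA-SYN-0010	Deletion	455	11	96	TRUE
TCF7L2	TCGA-SYN-0026	Silent	63	55	151	FALSE
SOX9	TCGA-SYN-0040	Frame_Shift_Ins	275	23	86	TRUE
TCF7L2	TCGA-SYN-0005	Frame_Shift_Del	388	13	188	FALSE
TCF7L2	TCGA-SYN-0030	Frame_Shift_Del	333	108	121	TRUE
SOX9	TCGA-SYN-0003	Deletion	158	43	76	FALSE
APC	TCGA-SYN-0021	Missense_Mutation	288	84	69	TRUE
TP53	TCGA-SYN-0031	Nonsense_Mutation	412	99	88	TRUE
KRAS	TCGA-SYN-0002	Missense_Mutation	92		161	FALSE
TCF7L2	TCGA-SYN-0030	Silent	6	61	77	TRUE
SOX9	TCGA-SYN-0001	Splice_Site	136	99	190	TRUE
TP53	TCGA-SYN-0011	Frame_Shift_Del	451	13	97	TRUE
SOX9	TCGA-SYN-0013	Missense_Mutation	375	14	192	FALSE
TCF7L2	TCGA-SYN-0033	Silent	50	111	88	FALSE
TCF7L2	TCGA-SYN-0031	Frame_Shift_Del	132	114	119	TRUE
APC	TCGA-SYN-0004	Splice_Site	122	62	71	TRUE
TP53	TCGA-SYN-0017	Missense_Mutation	306	17	87	TRUE
KRAS	TCGA-SYN-0002	Missense_Mutation	486	93	183	TRUE
SOX9	TCGA-SYN-0008	Missense_Mutation	268	44	89	TRUE
TCF7L2	TCGA-SYN-0003	Missense_Mutation	464	20	62	TRUE
SOX9	TCGA-SYN-0004	Frame_Shift_Ins	189	36	66	TRUE
APC	TCGA-SYN-0009	Frame_Shift_Ins	82	48	38	FALSE
APC	TCGA-SYN-0040	Missense_Mutation	315	41	145	TRUE
KRAS	TCGA-SYN-0037	Missense_Mutation	188	67	138	TRUE
TCF7L2	TCGA-SYN-0025	Missense_Mutation	44	61	85	TRUE
SOX9	TCGA-SYN-0010	Missense_Mutation	227	83	75	TRUE
APC	TCGA-SYN-0022	Nonsense_Mutation	423	94	184	TRUE
TCF7L2	TCGA-SYN-0031	Frame_Shift_Ins	27	72	140	TRUE
APC	TCGA-SYN-0009	Frame_Shift_Ins	12	119	102	TRUE
SOX9	TCGA-SYN-0026	Missense_Mutation	462	42	40	TRUE
TCF7L2	TCGA-SYN-0015	Splice_Site	454	80	110	TRUE
SOX9	TCGA-SYN-0020	Deletion	341	117	123	FALSE
TP53	TCGA-SYN-0024	Nonsense_Mutation	274	22	62	TRUE
SOX9	TCGA-SYN-0014	Missense_Mutation	159	46	59	TRUE
TP53	TCGA-SYN-0004	Missense_Mutation	470	56	176	TRUE
TCF7L2	TCGA-SYN-0009	In_Frame_Del	474	0	0	FALSE
APC	TCGA-SYN-0027	In_Frame_Del	478	59	149	TRUE
TCF7L2	TCGA-SYN-0034	Frame_Shift_Del	240	53	181	TRUE
TP53	TCGA-SYN-0032	Frame_Shift_Del	101	60	83	TRUE
APC	TCGA-SYN-0015	Splice_Site	370	111	52	TRUE
APC	TCGA-SYN-0030	Frame_Shift_Del	379	113	162	FALSE
APC	TCGA-SYN-0009	Frame_Shift_Ins	65	10	76	TRUE
TP53	TCGA-SYN-0028	Nonsense_Mutation	446	72	165	TRUE
KRAS	TCGA-SYN-0024	Nonsense_Mutation	128	68	136	TRUE
TP53	TCGA-SYN-0006	Frame_Shift_Del	196	11	187	TRUE
TP53	TCGA-SYN-0029	Frame_Shift_Ins	20	46	157	TRUE
KRAS	TCGA-SYN-0026	Nonsense_Mutation	14	94	177	TRUE
SOX9	TCGA-SYN-0010	Deletion	333	29	145	TRUE
TP53	TCGA-SYN-0035	Frame_Shift_Ins	324	102	88	TRUE
TP53	TCGA-SYN-0038	Nonsense_Mutation	289	98	196	TRUE
KRAS	TCGA-SYN-0025	Frame_Shift_Del	132	15	141	TRUE
KRAS	TCGA-SYN-0038	Nonsense_Mutation	112	89	97	TRUE
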