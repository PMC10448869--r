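gene	total_oncogenic	diploid_or_gain_samples	het_lt50	proportion_published	max_allele_fraction	pct_samples_mutated	het_preferential
TP53	328	78	48	0.14634	1	60	FALSE
KRAS	219	197	144	0.65753	0.95	42	TRUE
PIK3CA	147	141	130	0.88435	0.86	28	TRUE
SMAD4	57	20	17	0.29825	0.89	16	FALSE
TCF7L2	40	29	24	0.60000	0.74	14	TRUE
SOX9	54	46	41	0.75926	0.89	13	TRUE
BRAF	56	55	49	0.87500	0.7	12	TRUE
ARID1A	46	41	38	0.82609	0.64	11	TRUE
RNF43	38	36	33	0.86842	0.76	10	TRUE
PTEN	46	37	34	0.73913	0.71	9	TRUE
AXIN2	22	20	20	0.90909	0.58	7	TRUE
CTNNB1	18	16	10	0.55556	0.85	7	TRUE
ERBB2	9	9	5	0.55556	0.96	7	TRUE
NRAS	30	22	15	0.50000	0.86	7	FALSE
SMAD2	25	15	12	0.48000	0.81	7	FALSE
MYC	4	4	4	1.00000	0.47	6	TRUE
SMAD3	13	9	5	0.38462	0.88	6	FALSE
RB1	7	7	7	1.00000	0.39	5	TRUE
CDH1	8	7	7	0.87500	0.52	4	TRUE
RBM10	8	7	3	0.37500	0.91	4	FALSE
CDKN2A	2	2	2	1.00000	0.38	2.3	TRUE
RHOA	4	4	4	1.00000	0.38	1.7	TRUE
CSMD3	156	154	149	0.95513	0.68	23	TRUE
CSMD1	147	113	107	0.72789	0.91	23	TRUE
MUC6	38	37	35	0.92105	0.61	6	TRUE
FBXL7	33	31	26	0.78788	0.75	6	TRUE
PCBP1	25	25	24	0.96000	0.5	5	TRUE
TCF4	19	18	17	0.89474	0.5	5	TRUE
SOX11	14	12	11	0.78571	0.55	2.5	TRUE
TCF7	10	10	8	0.80000	0.55	2.5	TRUE
TGFB1	8	8	8	1.00000	0.35	1.5	TRUE
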