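gene_set	term	aspect	query_item	query_total	bg_item	bg_total	p_printed	fdr_printed
silk	amino acid transport	P	10	900	52	39203	2.80E-07	0.00021
silk	protein amino acid phosphorylation	P	93	900	2387	39203	2.70E-06	0.00082
silk	oligopeptide transport	P	12	900	105	39203	6.10E-06	0.0011
silk	fatty acid metabolic process	P	14	900	187	39203	0.00013	0.014
silk	lipid transport	P	10	900	104	39203	0.00015	0.014
silk	cell wall macromolecule catabolic process	P	8	900	73	39203	0.00028	0.022
silk	chitin catabolic process	P	6	900	43	39203	0.00044	0.03
silk	drug transport	P	11	900	154	39203	0.00097	0.05
silk	integral to membrane	C	75	900	2156	39203	0.00055	0.029
silk	peroxisome	C	5	900	33	39203	0.0009	0.029
silk	protein serine/threonine kinase activity	F	92	900	2248	39203	4.40E-07	0.00013
silk	monooxygenase activity	F	33	900	553	39203	1.30E-06	0.00029
silk	heme binding	F	43	900	876	39203	6.20E-06	0.0007
silk	acyltransferase activity	F	16	900	187	39203	8.80E-06	0.0008
silk	amino acid transmembrane transporter activity	F	6	900	28	39203	3.60E-05	0.0024
silk	electron carrier activity	F	42	900	914	39203	3.50E-05	0.0024
silk	transferase activity, transferring hexosyl groups	F	28	900	542	39203	9.40E-05	0.0053
silk	sugar binding	F	12	900	150	39203	0.00021	0.0095
silk	secondary active transmembrane transporter activity	F	22	900	421	39203	0.00042	0.018
silk	chitinase activity	F	6	900	43	39203	0.00044	0.018
silk	lipid binding	F	13	900	202	39203	0.00093	0.035
silk	drug transmembrane transporter activity	F	11	900	154	39203	0.00097	0.035
conserved	protein amino acid phosphorylation	P	67	294	2387	39203	1.50E-17	8.60E-15
conserved	oligopeptide transport	P	12	294	105	39203	4.10E-11	2.90E-09
conserved	fatty acid biosynthesis process	P	10	294	159	39203	5.00E-07	2.60E-05
conserved	apoptosis	P	8	294	168	39203	5.00E-05	0.002
conserved	regulation of transcription	P	46	294	3352	39203	0.00024	0.0069
conserved	multidrug transport	P	5	294	79	39203	0.00035	0.0076
conserved	protein serine/threonine kinase activity	F	67	294	2248	39203	8.30E-19	2.80E-16
conserved	ATP binding	F	85	294	5133	39203	1.50E-09	6.30E-08
conserved	acyltransferase activity	F	11	294	187	39203	2.70E-07	5.70E-06
conserved	sugar binding	F	10	294	150	39203	2.90E-07	5.80E-06
conserved	transcription factor activity	F	28	294	1390	39203	7.50E-06	0.00012
conserved	sequence-specific DNA binding	F	22	294	985	39203	1.40E-05	0.00022
conserved	transporter activity	F	37	294	2411	39203	0.00011	0.0015
distinct	lipid transport	P	9	476	104	39203	6.00E-06	0.0034
distinct	amino acid transport	P	6	476	52	39203	4.20E-05	0.0079
distinct	chitin catabolic process	P	5	476	43	39203	0.00018	0.025
distinct	tetracycline transport	P	6	476	75	39203	0.00033	0.029
distinct	response to antibiotic	P	6	476	84	39203	0.0006	0.038
distinct	amino acid transmembrane transporter activity	F	6	476	28	39203	1.00E-06	0.00019
distinct	chitinase activity	F	5	476	43	39203	0.00018	0.022
distinct	small conjugating protein ligase activity	F	13	476	324	39203	0.00023	0.022
distinct	tetracycline transporter activity	F	6	476	75	39203	0.00033	0.022
distinct	lipid binding	F	9	476	202	39203	0.00096	0.049
distinct	coenzyme binding	F	20	476	734	39203	0.001	0.049
distinct	integral to membrane	C	51	476	2156	39203	1.90E-05	0.0016
distinct	peroxisome	C	5	476	33	39203	4.80E-05	0.0016
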