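gene	accession	significance	ratio_cd9pep_sc	ratio_cd63pep_sc	description
SRPX	P78539	112.75	0.29	0.52	Sushi repeat-containing protein SRPX OS = Homo sapiens OX = 9606 GN = SRPX PE = 1 SV = 1
C1QBP	Q07021	200	0.33	2.71	Complement component 1 Q subcomponent-binding protein mitochondrial OS = Homo sapiens OX = 9606 GN = C1QBP PE = 1 SV = 1
MDK	P21741	40.04	0.39	0.83	Midkine OS = Homo sapiens OX = 9606 GN = MDK PE = 1 SV = 1
KRT1	P04264	90.94	0.44	0.3	Keratin type II cytoskeletal 1 OS = Homo sapiens OX = 9606 GN = KRT1 PE = 1 SV = 6
THBS1	P07996	48.85	0.44	0.81	Thrombospondin-1 OS = Homo sapiens OX = 9606 GN = THBS1 PE = 1 SV = 2
KRT9	P35527	108.42	0.45	0.29	Keratin type I cytoskeletal 9 OS = Homo sapiens OX = 9606 GN = KRT9 PE = 1 SV = 3
PXDN	Q92626	40.85	0.46	0.58	Peroxidasin homolog OS = Homo sapiens OX = 9606 GN = PXDN PE = 1 SV = 2
RPL27	P61353	33.08	0.47	1.1	60S ribosomal protein L27 OS = Homo sapiens OX = 9606 GN = RPL27 PE = 1 SV = 2
KRT2	P35908	66.84	0.49	0.38	Keratin type II cytoskeletal 2 epidermal OS = Homo sapiens OX = 9606 GN = KRT2 PE = 1 SV = 2
RPL34	P49207	22.77	0.51	1.16	60S ribosomal protein L34 OS = Homo sapiens OX = 9606 GN = RPL34 PE = 1 SV = 3
KRT10	P13645	104.91	0.53	0.34	Keratin type I cytoskeletal 10 OS = Homo sapiens OX = 9606 GN = KRT10 PE = 1 SV = 6
THBS2	P35442	23.24	0.55	0.95	Thrombospondin-2 OS = Homo sapiens OX = 9606 GN = THBS2 PE = 1 SV = 2
COL18A1	P39060	111.95	0.61	1.57	Collagen alpha-1(XVIII) chain OS = Homo sapiens OX = 9606 GN = COL18A1 PE = 1 SV = 5
KRT5	P13647	44.17	0.63	0.37	Keratin type II cytoskeletal 5 OS = Homo sapiens OX = 9606 GN = KRT5 PE = 1 SV = 3
COL12A1	Q99715	22.05	0.63	1.13	Collagen alpha-1(XII) chain OS = Homo sapiens OX = 9606 GN = COL12A1 PE = 1 SV = 2
CCN1	O00622	65.49	0.64	1.5	Protein CYR61 OS = Homo sapiens OX = 9606 GN = CYR61 PE = 1 SV = 1
CHMP2A	O43633	23.5	0.65	0.56	Charged multivesicular body protein 2a OS = Homo sapiens OX = 9606 GN = CHMP2A PE = 1 SV = 1
ANXA2	P07355	40.21	0.67	0.51	Annexin A2 OS = Homo sapiens OX = 9606 GN = ANXA2 PE = 1 SV = 2
GPC1	P35052	39.05	0.69	1.74	Glypican-1 OS = Homo sapiens OX = 9606 GN = GPC1 PE = 1 SV = 2
KRT16	P08779	21.39	0.72	0.52	Keratin type I cytoskeletal 16 OS = Homo sapiens OX = 9606 GN = KRT16 PE = 1 SV = 4
NPM1	P06748	68	0.75	1.95	Nucleophosmin OS = Homo sapiens OX = 9606 GN = NPM1 PE = 1 SV = 2
EEF1A2	Q05639	20.56	0.79	0.54	Elongation factor 1-alpha 2 OS = Homo sapiens OX = 9606 GN = EEF1A2 PE = 1 SV = 1
LOXL2	Q9Y4K0	41.24	0.8	1.62	Lysyl oxidase homolog 2 OS = Homo sapiens OX = 9606 GN = LOXL2 PE = 1 SV = 1
HSPG2	P98160	43.16	0.86	1.51	Basement membrane-specific heparan sulfate proteoglycan core protein OS = Homo sapiens OX = 9606 GN = HSPG2 PE = 1 SV = 4
SDC4	P31431	52.84	0.91	1.89	Syndecan-4 OS = Homo sapiens OX = 9606 GN = SDC4 PE = 1 SV = 2
H1-4	P10412	58.18	1.01	0.22	Histone H1.4 OS = Homo sapiens OX = 9606 GN = HIST1H1E PE = 1 SV = 2
SRPX2	O60687	23.31	1.17	1.93	Sushi repeat-containing protein SRPX2 OS = Homo sapiens OX = 9606 GN = SRPX2 PE = 1 SV = 1
NCL	P19338	50.66	1.23	2.68	Nucleolin OS = Homo sapiens OX = 9606 GN = NCL PE = 1 SV = 3
PSMA1	P25786	23.38	1.27	0.62	Proteasome subunit alpha type-1 OS = Homo sapiens OX = 9606 GN = PSMA1 PE = 1 SV = 1
LTF	E7ER44	23.1	1.51	0.66	Lactotransferrin OS = Homo sapiens OX = 9606 GN = LTF PE = 1 SV = 1
ALB	P02768	25.98	1.54	0.99	Serum albumin OS = Homo sapiens OX = 9606 GN = ALB PE = 1 SV = 2
LAMA2	P24043	24.73	1.75	1.47	Laminin subunit alpha-2 OS = Homo sapiens OX = 9606 GN = LAMA2 PE = 1 SV = 4
LGALS3BP	Q08380	22.23	1.79	1.23	Galectin-3-binding protein OS = Homo sapiens OX = 9606 GN = LGALS3BP PE = 1 SV = 1
SLC38A2	Q96QD8	24.91	1.86	1.38	Sodium-coupled neutral amino acid transporter 2 OS = Homo sapiens OX = 9606 GN = SLC38A2 PE = 1 SV = 2
CD81	P60033	27.99	2.06	1.29	CD81 antigen OS = Homo sapiens OX = 9606 GN = CD81 PE = 1 SV = 1
GJC1	P36383	200	2.13	0.42	Gap junction gamma-1 protein OS = Homo sapiens OX = 9606 GN = GJC1 PE = 1 SV = 2
AHSA1	O95433	23.74	2.17	1.27	Activator of 90 kDa heat shock protein ATPase homolog 1 OS = Homo sapiens OX = 9606 GN = AHSA1 PE = 1 SV = 1
FABP5	Q01469	32.35	2.18	0.78	Fatty acid-binding protein epidermal OS = Homo sapiens OX = 9606 GN = FABP5 PE = 1 SV = 3
GNB2	P62879	33.59	2.23	1.63	Guanine nucleotide-binding protein G(I)/G(S)/G(T) subunit beta-2 OS = Homo sapiens OX = 9606 GN = GNB2 PE = 1 SV = 3
RAC1	P63000	27.6	2.27	1.63	Ras-related C3 botulinum toxin substrate 1 OS = Homo sapiens OX = 9606 GN = RAC1 PE = 1 SV = 1
HIST1H4A	P62805	47.29	2.35	1.58	Histone H4 OS = Homo sapiens OX = 9606 GN = HIST1H4A PE = 1 SV = 2
TUBB3	Q13509	24.47	2.44	2.02	Tubulin beta-3 chain OS = Homo sapiens OX = 9606 GN = TUBB3 PE = 1 SV = 2
TUBA1C	Q9BQE3	33.16	2.8	2.13	Tubulin alpha-1C chain OS = Homo sapiens OX = 9606 GN = TUBA1C PE = 1 SV = 1
S100A7	P31151	57.05	10.53	0.94	Protein S100-A7 OS = Homo sapiens OX = 9606 GN = S100A7 PE = 1 SV = 4
SERPINB3	P29508	153.52	14.21	0.85	Serpin B3 OS = Homo sapiens OX = 9606 GN = SERPINB3 PE = 1 SV = 2
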