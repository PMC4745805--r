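rank	accession	protein_name	present_ctr	present_pat	sensitivity_pct	n_pat_pos	ibaq_ratio	abundance_ppm
1	Q8N2U0	Transmembrane protein 256	5	16	94	15	140.39	4324
2	Q15847	Adipogenesis regulatory factor	4	15	81	13	18.99	369
3	Q6IAA8	Ragulator complex protein LAMTOR1	4	16	81	13	22.98	201
4	P13796	Plastin-2	14	16	75	12	3.15	256
5	P61019	Ras-related protein Rab-2A	14	16	75	12	3.55	1083
6	P20337	Ras-related protein Rab-3B	15	16	75	12	2.69	1138
7	O95716	Ras-related protein Rab-3D	15	16	75	12	2.24	2340
8	P51149	Ras-related protein Rab-7a	15	16	75	12	3.26	2317
9	P27449	V-type proton ATPase 16 kDa proteolipid subunit	0	12	75	12	3.55	861
10	Q687X5	Metalloreductase STEAP4	14	16	69	11	2.97	953
11	Q99497	Protein DJ-1	15	16	69	11	1.92	957
12	P25815	Protein S100-P	14	15	69	11	1.84	1351
13	Q96C24	Synaptotagmin-like protein 4	5	12	69	11	3.08	91
14	Q9NVJ2	ADP-ribosylation factor-like protein 8B	13	15	63	10	2.79	49
15	Q96QE2	Proton myo-inositol cotransporter	2	11	63	10	2.66	100
16	P20340	Ras-related protein Rab-6A	10	16	63	10	3.36	240
17	O43657	Tetraspanin-6	9	16	63	10	4.03	3067
18	P78369	Claudin-10	7	14	56	9	2.14	26
19	P57739	Claudin-2	2	12	56	9	3.00	69
20	O15551	Claudin-3	1	10	56	9	1.75	170
21	O60547	GDP-mannose 4.6 dehydratase	2	12	56	9	2.45	16
22	P46926	Glucosamine-6-phosphate isomerase 1	4	13	56	9	15.51	44
23	Q14108	Lysosome membrane protein 2	15	16	56	9	3.94	824
24	Q6NUT3	Major facilitator superfamily domain-containing protein 12	5	15	56	9	8.07	65
25	Q9BV36	Melanophilin	12	16	56	9	2.26	151
26	P35270	Sepiapterin reductase	10	14	56	9	2.16	114
27	Q9BRA2	Thioredoxin domain-containing protein 17	15	16	56	9	2.35	288
28	Q9BUT1	3-hydroxybutyrate dehydrogenase type 2	14	16	50	8	2.26	389
29	P62158	Calmodulin	15	16	50	8	6.30	4764
30	Q9Y646	Carboxypeptidase Q	1	8	50	8	5.80	51
31	Q14254	Flotillin-2	14	16	50	8	2.89	541
32	Q08380	Galectin-3-binding protein	15	16	50	8	1.99	678
33	Q99571	P2X purinoceptor 4	6	13	50	8	2.36	76
34	Q9Y3R5	Protein dopey-2	12	16	50	8	2.99	218
35	P06703	Protein S100-A6	15	16	50	8	0.48	1853
36	Q15286	Ras-related protein Rab-35	15	16	50	8	0.57	245
37	P67775	Serine/threonine-protein phosphatase 2A catalytic subunit alpha isoform	11	14	50	8	16.91	41
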