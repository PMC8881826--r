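index	label	lobe	hemisphere
1	Precentral_L	frontal	L
2	Frontal_Sup_L	frontal	L
3	Frontal_Sup_Orb_L	frontal	L
4	Frontal_Mid_L	frontal	L
5	Frontal_Mid_Orb_L	frontal	L
6	Frontal_Inf_Oper_L	frontal	L
7	Frontal_Inf_Tri_L	frontal	L
8	Frontal_Inf_Orb_L	frontal	L
9	Rolandic_Oper_L	frontal	L
10	Supp_Motor_Area_L	frontal	L
11	Olfactory_L	frontal	L
12	Frontal_Sup_Medial_L	frontal	L
13	Frontal_Med_Orb_L	frontal	L
14	Rectus_L	frontal	L
15	Paracentral_Lobule_L	frontal	L
16	Postcentral_L	parietal	L
17	Parietal_Sup_L	parietal	L
18	Parietal_Inf_L	parietal	L
19	SupraMarginal_L	parietal	L
20	Angular_L	parietal	L
21	Precuneus_L	parietal	L
22	Calcarine_L	occipital	L
23	Cuneus_L	occipital	L
24	Lingual_L	occipital	L
25	Occipital_Sup_L	occipital	L
26	Occipital_Mid_L	occipital	L
27	Occipital_Inf_L	occipital	L
28	Insula_L	temporal	L
29	Cingulum_Ant_L	temporal	L
30	Cingulum_Mid_L	temporal	L
31	Cingulum_Post_L	temporal	L
32	ParaHippocampal_L	temporal	L
33	Fusiform_L	temporal	L
34	Heschl_L	temporal	L
35	Temporal_Sup_L	temporal	L
36	Temporal_Pole_Sup_L	temporal	L
37	Temporal_Mid_L	temporal	L
38	Temporal_Pole_Mid_L	temporal	L
39	Temporal_Inf_L	temporal	L
40	Precentral_R	frontal	R
41	Frontal_Sup_R	frontal	R
42	Frontal_Sup_Orb_R	frontal	R
43	Frontal_Mid_R	frontal	R
44	Frontal_Mid_Orb_R	frontal	R
45	Frontal_Inf_Oper_R	frontal	R
46	Frontal_Inf_Tri_R	frontal	R
47	Frontal_Inf_Orb_R	frontal	R
48	Rolandic_Oper_R	frontal	R
49	Supp_Motor_Area_R	frontal	R
50	Olfactory_R	frontal	R
51	Frontal_Sup_Medial_R	frontal	R
52	Frontal_Med_Orb_R	frontal	R
53	Rectus_R	frontal	R
54	Paracentral_Lobule_R	frontal	R
55	Postcentral_R	parietal	R
56	Parietal_Sup_R	parietal	R
57	Parietal_Inf_R	parietal	R
58	SupraMarginal_R	parietal	R
59	Angular_R	parietal	R
60	Precuneus_R	parietal	R
61	Calcarine_R	occipital	R
62	Cuneus_R	occipital	R
63	Lingual_R	occipital	R
64	Occipital_Sup_R	occipital	R
65	Occipital_Mid_R	occipital	R
66	Occipital_Inf_R	occipital	R
67	Insula_R	temporal	R
68	Cingulum_Ant_R	temporal	R
69	Cingulum_Mid_R	temporal	R
70	Cingulum_Post_R	temporal	R
71	ParaHippocampal_R	temporal	R
72	Fusiform_R	temporal	R
73	Heschl_R	temporal	R
74	Temporal_Sup_R	temporal	R
75	Temporal_Pole_Sup_R	temporal	R
76	Temporal_Mid_R	temporal	R
77	Temporal_Pole_Mid_R	temporal	R
78	Temporal_Inf_R	temporal	R
79	Hippocampus_L	subcortical	L
80	Hippocampus_R	subcortical	R
81	Amygdala_L	subcortical	L
82	Amygdala_R	subcortical	R
83	Caudate_L	subcortical	L
84	Caudate_R	subcortical	R
85	Putamen_L	subcortical	L
86	Putamen_R	subcortical	R
87	Pallidum_L	subcortical	L
88	Pallidum_R	subcortical	R
89	Thalamus_L	subcortical	L
90	Thalamus_R	subcortical	R
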