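pair	wol_third	wol_syn	wol_bp	nuc_third	nuc_syn	nuc_bp	mt_third	mt_syn	mt_bp	r_wn_third	r_wn_syn	r_mw_third	r_mw_syn	r_mn_third	r_mn_syn
Nasonia_longicornis/N_giraulti	0.2	0.3	4486	NA	1.12	4135	NA	45.24	2241	NA	0.27	NA	150.8	NA	40.4
Drosophila_bicornuta/D_barbarae	2.4	3.7	620685	12.3	19.3	37401	15.7	28.0	11030	0.20	0.19	6.54	7.57	1.28	1.45
Brugia_malayi/B_pahangi	0.88	1.4	598257	1.94	3.10	33099	28.2	43.7	10361	0.45	0.45	32.0	31.2	14.5	14.1
N_ferruginata/N_panzeri	0.29	0.46	613605	1.73	2.39	36402	2.53	4.95	9249	0.17	0.19	8.72	10.76	1.46	2.07
N_ferruginata/N_flava	0.27	0.43	613605	1.43	2.15	36402	2.61	5.27	9249	0.19	0.20	9.67	12.26	1.83	2.45
N_ferruginata/N_leucophtalma	0.27	0.43	613605	1.47	2.13	36402	2.22	4.45	9249	0.18	0.20	8.22	10.35	1.51	2.09
N_panzeri/N_flava	0.032	0.051	613605	0.99	1.29	36402	2.42	4.94	9249	0.032	0.040	75.6	96.9	2.44	3.83
N_panzeri/N_leucophtalma	0.033	0.051	613605	1.00	1.27	36402	2.25	4.52	9249	0.033	0.040	68.2	88.6	2.25	3.56
N_flava/N_leucophtalma	0.0088	0.011	613605	0.65	1.06	36402	1.34	2.62	9249	0.014	0.010	152.3	238.2	2.06	2.47
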