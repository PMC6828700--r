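gene	carriers_maf001_cases	n_de_novo	eur_frequency	corrected_p	n_lp_vus	pli	hi_percentile	rvis_raw	rvis_percentile	z_missense
AGAP1	8	1	0.006	3.33E-4	4	1.00	17.79	-1.14	10.60	1.41
ERLIN1	3	0	0.0002	4.03E-3	2	0.18	19.99	-0.06	46.69	1.89
ZDHHC9	3	0	0.0002	4.03E-3	2	0.74	13.32	-0.88	14.42	2.64
PROC	5	0	0.002	4.59E-2	4	0	66.64	-0.76	19.23	0.96
KIF1A	9	1	0.03	0.075	3	1.00	50.61	-2.71	1.35	5.41
SCN8A	4	1	0.02	0.13	1	1.0	5.52	-3.46	0.66	7.94
TENM1	11	0	0.001	0.15	1	1.00	1.32	-1.52	4.70	3.63
MYO1F	11	0	0.0001	0.15	4	0.16	45.46	0.49	71.22	2.93
ENPP4	5	0	0.004	0.90	2	0.41	44.16	0.25	61.40	0.44
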