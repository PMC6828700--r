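gene	sample_id	inheritance	gnomad_af	variant	consequence	cadd_phred	gerp	mtr_centile	polyphen2_hvar	mutation_taster	prior_case	prior_variant
ADCY3	P443	Paternal	0	c.1138C>T:p.R380W	missense	33	4.60	0.79	D	D	TRUE	TRUE
ADCY3	P947	Unknown	4.07E-06	c.1789C>T:p.R597*	stop_gain	43	4.21	-	-	A	FALSE	FALSE
ADCY3	16922	Not maternal	2.04E-05	c.2042C>A:p.A681D	missense	26.7	5.40	49.08	D	D	FALSE	FALSE
AGAP1	P033	De novo	0	c.957+1G>A	splice	27.3	5.08	-	-	D	TRUE	TRUE
AGAP1	P738	De novo	1.94E-04	c.1400C>G:p.P467R	missense	27.4	4.21	77.01	P	D	FALSE	FALSE
AGAP1	P1126	Not maternal	0	c.1232C>T:p.P411L	missense	33	4.66	11.42	D	D	FALSE	FALSE
COPS3	16458	Not maternal	0	c.7A>T:p.S3C	missense	24.6	5.52	92.08	P	D	FALSE	FALSE
GAD1	P176	Not maternal	4.06E-06	c.773A>G:p.Y258C	missense	26.3	5.67	33.11	D	D	FALSE	FALSE
GAD1	10635	Not maternal	1.65E-05	c.1208C>T:p.P403L	missense	34	5.91	20.17	D	D	FALSE	FALSE
INHBB	P058	De novo	8.21E-06	c.472C>T:p.R158C	missense	26.2	5.09	30.77	B	D	TRUE	TRUE
KDM7A	P105	De novo	0	c.2180C>G:p.S727W	missense	34	5.85	36.31	D	D	TRUE	TRUE
KDM7A	11348	Unknown	1.22E-05	c.484G>T:p.V162F	missense	32	5.37	20.59	D	D	FALSE	FALSE
MAOB	P025	X-linked	0	c.1138-1G>A	splice	23.8	6.17	-	-	D	TRUE	TRUE
MAOB	P216	X-linked	0	c.980C>T:p.T327M	missense	32	5.47	25.58	D	D	FALSE	FALSE
MAOB	P915	Not maternal, also present in twin	0	c.980C>T:p.T327M	missense	32	5.47	25.58	D	D	FALSE	FALSE
NAA35	P117	De novo	0	c.1596G>T:p.W532C	missense	33	5.40	20.14	D	D	TRUE	TRUE
NAA35	P783	Unknown	0	c.134T>C:p.L45S	missense	27	3.94	28.97	D	D	FALSE	FALSE
RNF214	P007	De novo	0	c.1363C>T:p.P455S	missense	23.4	4.76	97.16	D	D	TRUE	TRUE
SLC6A3	P042	Not maternal	0	c.1199C>T:p.T400M	missense	18.55	4.69	11.78	D	D	TRUE	FALSE
SLC6A3	P082	Paternal	0	c.253C>T:p.R85W	missense	32	1.46	8.54	D	D	TRUE	FALSE
SREK1	P436	De novo	4.09E-06	c.169C>T:p.P57S	missense	18.21	5.61	7.20	P	D	TRUE	TRUE
SREK1	10894	Not maternal	8.12E-06	c.937C>T:p.R313C	missense	24.3	5.40	91.68	D	D	FALSE	FALSE
TENM1	P026	Paternal	0	c.6118G>C:p.D2040H	missense	23.6	5.44	14.87	D	D	TRUE	TRUE
TENM1	10397	Not maternal	0	c.6584G>A:p.R2195Q	missense	25.4	5.52	88.08	D	D	FALSE	FALSE
UBXN7	P067	De novo	0	c.310G>A:p.A104T	missense	20.1	4.47	62.04	P	D	TRUE	TRUE
ZMYM3	11451	Not maternal	0	c.857G>A:p.R286H	missense	34	4.90	8.38	B	P	FALSE	FALSE
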