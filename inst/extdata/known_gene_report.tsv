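sample_id	gene	inheritance	gnomad_af	variant	dbsnp	acmg_class	prior_case	prior_variant
P009	MAST1	De novo	0	c.1499C>T:p.P500L	NA	likely_pathogenic	TRUE	TRUE
P015	PAK3	X-linked	0	c.1477C>T:p.R493C	NA	VUS	TRUE	TRUE
P026	KDM5C	De novo	0	c.1238C>T:p.P413L	rs1057518697	pathogenic	TRUE	TRUE
P033	COL4A1	Paternal	0	c.2413G>A:p.G805R	NA	pathogenic	TRUE	FALSE
P035	COL4A1	Not maternal	8.12E-06	c.136G>A:p.G46R	NA	VUS	TRUE	FALSE
P052	PROC	Paternal	2.53E-05	c.169C>T:p.R57W	rs757583846	pathogenic	TRUE	FALSE
P052	PROC	Maternal	2.53E-05	c.814C>T:p.R272C	rs121918154	pathogenic	TRUE	FALSE
P106	COL4A1	Paternal	0	c.4516A>G:p.N1506D	NA	VUS	TRUE	FALSE
P174	KIF1A	Not maternal, father unavailable	0	c.296C>T:p.T99M	rs387906799	pathogenic	FALSE	FALSE
P204	COL4A1	Not maternal	0	c.2494G>A:p.G832R	rs797044867	pathogenic	FALSE	FALSE
P718	NT5C2	Homozygous-identical by descent	0	c.115C>T:p.R39*	NA	pathogenic	FALSE	FALSE
P724	L1CAM	X-linked	0	c.2137C>T:p.P713S	NA	likely_pathogenic	FALSE	FALSE
P773	MAST1	Not maternal	8.12E-06	c.1066G>A:p.D356N	NA	VUS	FALSE	FALSE
P781	KIF1A	De novo	0	c.946C>T:p.R316W	rs672601370	pathogenic	FALSE	FALSE
P904	SCN8A	De novo, also present in identical twin	4.06E-06	c.4724C>T:p.A1575V	NA	VUS	FALSE	FALSE
P915	HUWE1	Not maternal, also present in twin	5.60E-06	c.6391T>A:p.L2131M	NA	likely_benign	FALSE	FALSE
P968	BRWD3	Unknown	0	c.3088G>A:p.V1030I	NA	VUS	FALSE	FALSE
P981	COL4A1	Not maternal	6.63E-05	c.2447C>T:p.P816L	NA	VUS	FALSE	FALSE
P1102	HUWE1	Paternal	1.69E-05	c.8558A>T:p.E2853V	NA	VUS	FALSE	FALSE
P1116	COL4A1	Maternal	7.21E-05	c.4856G>A:p.R1619H	NA	VUS	FALSE	FALSE
P1147	IQSEC2	Paternal	0	c.1753C>T:p.R585W	NA	likely_benign	FALSE	FALSE
10249	HUWE1	Unknown	5.60E-06	c.6500C>T:p.A2167V	NA	VUS	FALSE	FALSE
10894	SYNGAP1	Not maternal	0	c.3436C>G:p.P1146A	NA	VUS	FALSE	FALSE
14986	MAST1	Paternal	1.44E-05	c.421G>A:p.E141K	NA	VUS	FALSE	FALSE
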