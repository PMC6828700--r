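gene	known_disease_gene	candidate_gene
ADCY3	FALSE	TRUE
AGAP1	FALSE	TRUE
BRWD3	TRUE	FALSE
COL4A1	TRUE	FALSE
COPS3	FALSE	TRUE
CPCAND001	FALSE	TRUE
CPCAND002	FALSE	TRUE
CPCAND003	FALSE	TRUE
CPCAND004	FALSE	TRUE
CPCAND005	FALSE	TRUE
CPCAND006	FALSE	TRUE
CPCAND007	FALSE	TRUE
CPCAND008	FALSE	TRUE
CPCAND009	FALSE	TRUE
CPCAND010	FALSE	TRUE
CPCAND011	FALSE	TRUE
CPCAND012	FALSE	TRUE
CPCAND013	FALSE	TRUE
CPCAND014	FALSE	TRUE
CPCAND015	FALSE	TRUE
CPCAND016	FALSE	TRUE
CPCAND017	FALSE	TRUE
CPCAND018	FALSE	TRUE
CPCAND019	FALSE	TRUE
CPCAND020	FALSE	TRUE
CPCAND021	FALSE	TRUE
CPCAND022	FALSE	TRUE
CPCAND023	FALSE	TRUE
CPCAND024	FALSE	TRUE
CPCAND025	FALSE	TRUE
CPCAND026	FALSE	TRUE
CPCAND027	FALSE	TRUE
CPCAND028	FALSE	TRUE
CPCAND029	FALSE	TRUE
CPCAND030	FALSE	TRUE
CPCAND031	FALSE	TRUE
CPCAND032	FALSE	TRUE
CPCAND033	FALSE	TRUE
CPCAND034	FALSE	TRUE
CPCAND035	FALSE	TRUE
CPCAND036	FALSE	TRUE
CPCAND037	FALSE	TRUE
CPCAND038	FALSE	TRUE
CPCAND039	FALSE	TRUE
CPCAND040	FALSE	TRUE
CPCAND041	FALSE	TRUE
CPCAND042	FALSE	TRUE
CPCAND043	FALSE	TRUE
CPCAND044	FALSE	TRUE
CPCAND045	FALSE	TRUE
CPCAND046	FALSE	TRUE
CPCAND047	FALSE	TRUE
CPCAND048	FALSE	TRUE
CPCAND049	FALSE	TRUE
CPCAND050	FALSE	TRUE
CPCAND051	FALSE	TRUE
CPCAND052	FALSE	TRUE
CPCAND053	FALSE	TRUE
CPCAND054	FALSE	TRUE
CPCAND055	FALSE	TRUE
CPCAND056	FALSE	TRUE
CPCAND057	FALSE	TRUE
CPCAND058	FALSE	TRUE
CPCAND059	FALSE	TRUE
CPCAND060	FALSE	TRUE
CPCAND061	FALSE	TRUE
CPCAND062	FALSE	TRUE
CPCAND063	FALSE	TRUE
CPCAND064	FALSE	TRUE
CPCAND065	FALSE	TRUE
CPCAND066	FALSE	TRUE
CPCAND067	FALSE	TRUE
CPCAND068	FALSE	TRUE
CPCAND069	FALSE	TRUE
CPCAND070	FALSE	TRUE
CPCAND071	FALSE	TRUE
CPCAND072	FALSE	TRUE
CPCAND073	FALSE	TRUE
CPCAND074	FALSE	TRUE
CPCAND075	FALSE	TRUE
CPCAND076	FALSE	TRUE
CPCAND077	FALSE	TRUE
CPCAND078	FALSE	TRUE
ENPP4	FALSE	TRUE
ERLIN1	FALSE	TRUE
GAD1	FALSE	TRUE
HUWE1	TRUE	FALSE
INHBB	FALSE	TRUE
IQSEC2	TRUE	FALSE
KDM5C	TRUE	FALSE
KDM7A	FALSE	TRUE
KIF1A	TRUE	FALSE
L1CAM	TRUE	FALSE
MAOB	FALSE	TRUE
MAST1	TRUE	FALSE
MTMR1	FALSE	TRUE
MYO1F	FALSE	TRUE
NAA35	FALSE	TRUE
NT5C2	TRUE	FALSE
PAK3	TRUE	FALSE
PCBP3	FALSE	TRUE
PROC	TRUE	FALSE
RNF214	FALSE	TRUE
SCN8A	TRUE	FALSE
SLC6A3	FALSE	TRUE
SREK1	FALSE	TRUE
SYNGAP1	TRUE	FALSE
TENM1	FALSE	TRUE
TUBA1A	TRUE	FALSE
UBXN7	FALSE	TRUE
ZDHHC9	FALSE	TRUE
ZMYM3	FALSE	TRUE
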