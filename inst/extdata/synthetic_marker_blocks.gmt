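A	synthetic planted marker block (generator default config)	GENE0001	GENE0002	GENE0003	GENE0004	GENE0005	GENE0006	GENE0007	GENE0008	GENE0009	GENE0010	GENE0011	GENE0012	GENE0013	GENE0014	GENE0015	GENE0016	GENE0017	GENE0018	GENE0019	GENE0020	GENE0021	GENE0022	GENE0023	GENE0024	GENE0025	GENE0026	GENE0027	GENE0028	GENE0029	GENE0030	GENE0031	GENE0032	GENE0033	GENE0034	GENE0035	GENE0036	GENE0037	GENE0038	GENE0039	GENE0040
B	synthetic planted marker block (generator default config)	GENE0041	GENE0042	GENE0043	GENE0044	GENE0045	GENE0046	GENE0047	GENE0048	GENE0049	GENE0050	GENE0051	GENE0052	GENE0053	GENE0054	GENE0055	GENE0056	GENE0057	GENE0058	GENE0059	GENE0060	GENE0061	GENE0062	GENE0063	GENE0064	GENE0065	GENE0066	GENE0067	GENE0068	GENE0069	GENE0070	GENE0071	GENE0072	GENE0073	GENE0074	GENE0075	GENE0076	GENE0077	GENE0078	GENE0079	GENE0080
C	synthetic planted marker block (generator default config)	GENE0081	GENE0082	GENE0083	GENE0084	GENE0085	GENE0086	GENE0087	GENE0088	GENE0089	GENE0090	GENE0091	GENE0092	GENE0093	GENE0094	GENE0095	GENE0096	GENE0097	GENE0098	GENE0099	GENE0100	GENE0101	GENE0102	GENE0103	GENE0104	GENE0105	GENE0106	GENE0107	GENE0108	GENE0109	GENE0110	GENE0111	GENE0112	GENE0113	GENE0114	GENE0115	GENE0116	GENE0117	GENE0118	GENE0119	GENE0120
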