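LABEL	TYPE	MEDICATIONS	SIZE	REVIEWED	TRUE_POSITIVE
RxNorm	resource	1922	25051	91	85
Mayo Clinic	resource	1696	34220	106	86
MedlinePlus	resource	1273	38323	105	82
SIDER 4.1	resource	1042	39116	102	78
WebMD	resource	2289	77035	126	95
Wikipedia	resource	1999	52325	111	82
1	stratum	2892	135787	174	87
2	stratum	1517	15789	88	65
3	stratum	939	5863	63	56
4	stratum	510	2451	60	56
5	stratum	233	1123	57	52
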