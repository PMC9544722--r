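id	dam	sire	cohort
F0001	NA	NA	1
F0002	NA	NA	1
F0003	NA	NA	1
F0004	NA	NA	1
F0005	NA	NA	1
F0006	NA	NA	1
F0007	NA	NA	1
F0008	NA	NA	1
F0009	NA	NA	1
F0010	NA	NA	1
I00013	NA	NA	2
I00014	NA	NA	2
I00020	NA	NA	2
I00028	NA	NA	3
I00029	NA	NA	3
I00030	NA	NA	3
I00031	NA	NA	3
I00034	NA	NA	3
I00037	NA	NA	3
I00038	NA	NA	3
I00062	NA	NA	8
I00067	NA	NA	8
I00068	NA	NA	8
I00069	NA	NA	8
I00071	NA	NA	9
I00081	NA	NA	10
I00016	F0001	NA	2
I00044	F0001	NA	4
I00045	F0001	NA	4
I00024	F0003	NA	2
I00025	F0003	NA	3
I00026	F0003	NA	3
I00017	F0004	NA	2
I00054	F0004	F0004	6
I00055	F0004	F0004	6
I00056	F0004	F0004	7
I00018	NA	F0005	2
I00019	NA	F0005	2
I00027	NA	F0006	3
I00042	F0004	F0006	4
I00043	F0004	F0006	4
I00047	F0004	F0006	5
I00048	F0004	F0006	5
I00021	NA	F0007	2
I00035	NA	F0007	3
I00036	NA	F0007	3
I00046	NA	F0007	4
I00052	NA	F0007	6
I00053	NA	F0007	6
I00022	NA	F0008	2
I00023	NA	F0008	2
I00032	F0001	F0008	3
I00015	F0009	NA	2
I00033	F0009	NA	3
I00039	F0009	NA	4
I00040	F0009	NA	4
I00051	F0009	NA	5
I00011	F0002	F0010	2
I00012	F0002	F0010	2
I00041	NA	F0010	4
I00049	F0001	F0010	5
I00050	F0001	F0010	5
I00065	I00031	I00014	8
I00066	I00031	I00014	8
I00074	I00031	I00014	9
I00079	I00031	I00014	10
I00080	I00031	I00014	10
I00086	I00031	I00014	11
I00064	NA	I00025	8
I00077	NA	I00025	9
I00078	NA	I00025	9
I00082	NA	I00025	10
I00083	NA	I00025	10
I00087	NA	I00025	11
I00090	NA	I00025	12
I00097	I00014	I00025	13
I00075	I00017	NA	9
I00076	I00017	NA	9
I00094	I00017	I00031	12
I00070	I00054	NA	8
I00057	I00046	NA	8
I00058	I00046	NA	8
I00059	I00046	NA	8
I00072	I00046	NA	9
I00088	I00046	I00017	11
I00089	I00046	I00017	11
I00091	I00046	I00017	12
I00092	I00046	I00017	12
I00093	I00046	I00017	12
I00095	I00046	I00017	13
I00096	I00046	I00017	13
I00063	NA	I00033	8
I00073	NA	I00033	9
I00084	I00046	I00033	10
I00085	I00046	I00033	10
I00060	I00039	NA	8
I00061	I00039	NA	8
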