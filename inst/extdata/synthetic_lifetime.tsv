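id	hatch_year	fitness	status	last_seen_year
F0001	1	0	dead	1
F0002	1	0	dead	1
F0003	1	0	dead	1
F0004	1	0	dead	1
F0005	1	0	dead	1
F0006	1	0	dead	1
F0007	1	0	dead	1
F0008	1	0	dead	1
F0009	1	0	dead	1
F0010	1	0	alive	15
I00013	2	0	alive	15
I00014	2	0	dead	2
I00020	2	0	dead	2
I00028	3	0	dead	3
I00029	3	0	dead	3
I00030	3	3	dead	9
I00031	3	0	dead	3
I00034	3	0	dead	3
I00037	3	0	dead	3
I00038	3	0	dead	3
I00062	8	4	dead	13
I00067	8	0	dead	8
I00068	8	0	dead	8
I00069	8	0	dead	8
I00071	9	0	dead	9
I00081	10	0	dead	10
I00016	2	0	dead	2
I00044	4	3	dead	9
I00045	4	0	dead	4
I00024	2	4	dead	4
I00025	3	0	alive	15
I00026	3	0	dead	3
I00017	2	0	dead	2
I00054	6	18	dead	13
I00055	6	5	dead	12
I00056	7	0	dead	7
I00018	2	0	dead	2
I00019	2	0	dead	2
I00027	3	0	dead	3
I00042	4	14	dead	12
I00043	4	0	dead	4
I00047	5	0	dead	5
I00048	5	0	dead	5
I00021	2	0	dead	2
I00035	3	0	dead	3
I00036	3	0	dead	3
I00046	4	0	dead	4
I00052	6	0	dead	6
I00053	6	0	dead	6
I00022	2	0	dead	2
I00023	2	0	dead	2
I00032	3	0	dead	3
I00015	2	0	dead	2
I00033	3	0	dead	3
I00039	4	0	dead	4
I00040	4	0	dead	4
I00051	5	0	alive	15
I00011	2	0	dead	2
I00012	2	5	dead	8
I00041	4	0	dead	4
I00049	5	0	dead	5
I00050	5	0	dead	5
I00065	8	0	dead	8
I00066	8	0	dead	8
I00074	9	0	dead	9
I00079	10	0	dead	10
I00080	10	0	dead	10
I00086	11	0	alive	15
I00064	8	0	dead	8
I00077	9	0	dead	9
I00078	9	4	dead	12
I00082	10	0	dead	10
I00083	10	0	dead	10
I00087	11	0	dead	11
I00090	12	0	dead	15
I00097	13	0	dead	13
I00075	9	0	dead	9
I00076	9	0	dead	9
I00094	12	0	dead	12
I00070	8	0	dead	8
I00057	8	0	dead	8
I00058	8	0	dead	8
I00059	8	0	dead	8
I00072	9	0	dead	9
I00088	11	0	dead	11
I00089	11	0	dead	11
I00091	12	3	dead	15
I00092	12	0	dead	12
I00093	12	0	dead	12
I00095	13	0	dead	13
I00096	13	1	dead	15
I00063	8	0	dead	8
I00073	9	0	dead	9
I00084	10	0	dead	10
I00085	10	0	dead	10
I00060	8	0	dead	8
I00061	8	0	dead	8
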