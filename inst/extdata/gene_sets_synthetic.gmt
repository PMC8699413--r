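SYNGO:0001	clustered locus program 1 (synthetic)	SYN_3_023	SYN_3_024	SYN_3_025	SYN_3_026	SYN_3_027	SYN_3_028	SYN_3_029	SYN_3_030	SYN_3_031	SYN_3_032	SYN_3_033	SYN_3_034	SYN_3_035	SYN_3_036	SYN_3_037	SYN_3_038	SYN_3_039	SYN_3_040	SYN_3_041	SYN_3_042	SYN_3_043	SYN_3_044	SYN_3_045	SYN_3_046	SYN_3_047	SYN_3_048	SYN_3_049	SYN_3_050	SYN_3_051	SYN_3_052
SYNGO:0002	clustered locus program 2 (synthetic)	SYN_1_076	SYN_1_077	SYN_1_078	SYN_1_079	SYN_1_080	SYN_1_081	SYN_1_082	SYN_1_083	SYN_1_084	SYN_1_085	SYN_1_086	SYN_1_087	SYN_1_088	SYN_1_089	SYN_1_090	SYN_2_001	SYN_2_002	SYN_2_003	SYN_2_004	SYN_2_005	SYN_2_006	SYN_2_007	SYN_2_008	SYN_2_009	SYN_2_010	SYN_2_011	SYN_2_012	SYN_2_013	SYN_2_014	SYN_2_015
SYNGO:0003	clustered locus program 3 (synthetic)	SYN_5_020	SYN_5_021	SYN_5_022	SYN_5_023	SYN_5_024	SYN_5_025	SYN_5_026	SYN_5_027	SYN_5_028	SYN_5_029	SYN_5_030	SYN_5_031	SYN_5_032	SYN_5_033	SYN_5_034	SYN_5_035	SYN_5_036	SYN_5_037	SYN_5_038	SYN_5_039	SYN_5_040	SYN_5_041	SYN_5_042	SYN_5_043	SYN_5_044	SYN_5_045	SYN_5_046	SYN_5_047	SYN_5_048	SYN_5_049
SYNGO:0004	clustered locus program 4 (synthetic)	SYN_1_062	SYN_1_063	SYN_1_064	SYN_1_065	SYN_1_066	SYN_1_067	SYN_1_068	SYN_1_069	SYN_1_070	SYN_1_071	SYN_1_072	SYN_1_073	SYN_1_074	SYN_1_075	SYN_1_076	SYN_1_077	SYN_1_078	SYN_1_079	SYN_1_080	SYN_1_081	SYN_1_082	SYN_1_083	SYN_1_084	SYN_1_085	SYN_1_086	SYN_1_087	SYN_1_088	SYN_1_089	SYN_1_090	SYN_2_001
SYNGO:0005	clustered locus program 5 (synthetic)	SYN_5_035	SYN_5_036	SYN_5_037	SYN_5_038	SYN_5_039	SYN_5_040	SYN_5_041	SYN_5_042	SYN_5_043	SYN_5_044	SYN_5_045	SYN_5_046	SYN_5_047	SYN_5_048	SYN_5_049	SYN_5_050	SYN_5_051	SYN_5_052	SYN_5_053	SYN_5_054	SYN_5_055	SYN_5_056	SYN_5_057	SYN_5_058	SYN_5_059	SYN_5_060	SYN_6_001	SYN_6_002	SYN_6_003	SYN_6_004
SYNGO:0006	clustered locus program 6 (synthetic)	SYN_4_006	SYN_4_007	SYN_4_008	SYN_4_009	SYN_4_010	SYN_4_011	SYN_4_012	SYN_4_013	SYN_4_014	SYN_4_015	SYN_4_016	SYN_4_017	SYN_4_018	SYN_4_019	SYN_4_020	SYN_4_021	SYN_4_022	SYN_4_023	SYN_4_024	SYN_4_025	SYN_4_026	SYN_4_027	SYN_4_028	SYN_4_029	SYN_4_030	SYN_4_031	SYN_4_032	SYN_4_033	SYN_4_034	SYN_4_035
SYNGO:0007	clustered locus program 7 (synthetic)	SYN_2_070	SYN_2_071	SYN_2_072	SYN_2_073	SYN_2_074	SYN_2_075	SYN_2_076	SYN_2_077	SYN_2_078	SYN_2_079	SYN_2_080	SYN_3_001	SYN_3_002	SYN_3_003	SYN_3_004	SYN_3_005	SYN_3_006	SYN_3_007	SYN_3_008	SYN_3_009	SYN_3_010	SYN_3_011	SYN_3_012	SYN_3_013	SYN_3_014	SYN_3_015	SYN_3_016	SYN_3_017	SYN_3_018	SYN_3_019
SYNGO:0008	clustered locus program 8 (synthetic)	SYN_2_052	SYN_2_053	SYN_2_054	SYN_2_055	SYN_2_056	SYN_2_057	SYN_2_058	SYN_2_059	SYN_2_060	SYN_2_061	SYN_2_062	SYN_2_063	SYN_2_064	SYN_2_065	SYN_2_066	SYN_2_067	SYN_2_068	SYN_2_069	SYN_2_070	SYN_2_071	SYN_2_072	SYN_2_073	SYN_2_074	SYN_2_075	SYN_2_076	SYN_2_077	SYN_2_078	SYN_2_079	SYN_2_080	SYN_3_001
SYNGO:0009	clustered locus program 9 (synthetic)	SYN_1_085	SYN_1_086	SYN_1_087	SYN_1_088	SYN_1_089	SYN_1_090	SYN_2_001	SYN_2_002	SYN_2_003	SYN_2_004	SYN_2_005	SYN_2_006	SYN_2_007	SYN_2_008	SYN_2_009	SYN_2_010	SYN_2_011	SYN_2_012	SYN_2_013	SYN_2_014	SYN_2_015	SYN_2_016	SYN_2_017	SYN_2_018	SYN_2_019	SYN_2_020	SYN_2_021	SYN_2_022	SYN_2_023	SYN_2_024
SYNGO:0010	clustered locus program 10 (synthetic)	SYN_3_057	SYN_3_058	SYN_3_059	SYN_3_060	SYN_3_061	SYN_3_062	SYN_3_063	SYN_3_064	SYN_3_065	SYN_3_066	SYN_3_067	SYN_3_068	SYN_3_069	SYN_3_070	SYN_4_001	SYN_4_002	SYN_4_003	SYN_4_004	SYN_4_005	SYN_4_006	SYN_4_007	SYN_4_008	SYN_4_009	SYN_4_010	SYN_4_011	SYN_4_012	SYN_4_013	SYN_4_014	SYN_4_015	SYN_4_016
SYNGO:0011	clustered locus program 11 (synthetic)	SYN_3_006	SYN_3_007	SYN_3_008	SYN_3_009	SYN_3_010	SYN_3_011	SYN_3_012	SYN_3_013	SYN_3_014	SYN_3_015	SYN_3_016	SYN_3_017	SYN_3_018	SYN_3_019	SYN_3_020	SYN_3_021	SYN_3_022	SYN_3_023	SYN_3_024	SYN_3_025	SYN_3_026	SYN_3_027	SYN_3_028	SYN_3_029	SYN_3_030	SYN_3_031	SYN_3_032	SYN_3_033	SYN_3_034	SYN_3_035
SYNGO:0012	clustered locus program 12 (synthetic)	SYN_5_012	SYN_5_013	SYN_5_014	SYN_5_015	SYN_5_016	SYN_5_017	SYN_5_018	SYN_5_019	SYN_5_020	SYN_5_021	SYN_5_022	SYN_5_023	SYN_5_024	SYN_5_025	SYN_5_026	SYN_5_027	SYN_5_028	SYN_5_029	SYN_5_030	SYN_5_031	SYN_5_032	SYN_5_033	SYN_5_034	SYN_5_035	SYN_5_036	SYN_5_037	SYN_5_038	SYN_5_039	SYN_5_040	SYN_5_041
SYNGO:0013	dispersed process 1 (synthetic)	SYN_8_006	SYN_4_044	SYN_1_065	SYN_3_004	SYN_4_012	SYN_5_013	SYN_2_077	SYN_4_004	SYN_8_025	SYN_6_011	SYN_4_010	SYN_8_003	SYN_2_059	SYN_2_069	SYN_1_085	SYN_5_014	SYN_7_015	SYN_3_019	SYN_2_012	SYN_4_005	SYN_2_064	SYN_6_017	SYN_3_009	SYN_4_024	SYN_2_041	SYN_7_010	SYN_1_033	SYN_1_082	SYN_6_021	SYN_3_029	SYN_5_010	SYN_3_058	SYN_4_057	SYN_3_068	SYN_2_050	SYN_7_013	SYN_5_058	SYN_1_043	SYN_2_047	SYN_1_067
SYNGO:0014	dispersed process 2 (synthetic)	SYN_6_047	SYN_2_017	SYN_2_014	SYN_2_041	SYN_2_030	SYN_4_035	SYN_1_055	SYN_8_024	SYN_4_009	SYN_4_050	SYN_7_001	SYN_3_065	SYN_2_002	SYN_3_009	SYN_8_005	SYN_5_034	SYN_3_037	SYN_2_006	SYN_5_031	SYN_1_058	SYN_3_052	SYN_4_040	SYN_2_076	SYN_2_058	SYN_7_004	SYN_2_011	SYN_5_020	SYN_2_064	SYN_6_015	SYN_5_009	SYN_5_010	SYN_5_021	SYN_4_008	SYN_3_062	SYN_1_020	SYN_1_035	SYN_1_078	SYN_3_008	SYN_6_044	SYN_2_080
SYNGO:0015	dispersed process 3 (synthetic)	SYN_1_089	SYN_1_031	SYN_7_030	SYN_6_018	SYN_3_030	SYN_8_007	SYN_5_022	SYN_5_019	SYN_2_014	SYN_1_083	SYN_6_035	SYN_3_055	SYN_8_010	SYN_4_031	SYN_1_011	SYN_1_082	SYN_7_038	SYN_5_027	SYN_4_054	SYN_5_004	SYN_4_012	SYN_3_006	SYN_4_047	SYN_1_042	SYN_1_026	SYN_1_049	SYN_1_029	SYN_4_035	SYN_1_067	SYN_3_011	SYN_1_047	SYN_3_035	SYN_1_028	SYN_3_044	SYN_7_040	SYN_7_012	SYN_1_004	SYN_7_002	SYN_2_043	SYN_3_067
SYNGO:0016	dispersed process 4 (synthetic)	SYN_4_024	SYN_2_073	SYN_7_030	SYN_5_030	SYN_4_052	SYN_7_032	SYN_6_027	SYN_2_065	SYN_2_019	SYN_1_051	SYN_2_044	SYN_3_031	SYN_1_005	SYN_1_050	SYN_6_036	SYN_4_043	SYN_2_036	SYN_6_022	SYN_3_021	SYN_3_049	SYN_1_033	SYN_1_075	SYN_5_003	SYN_1_003	SYN_2_012	SYN_7_039	SYN_5_040	SYN_2_080	SYN_1_028	SYN_3_042	SYN_1_073	SYN_3_016	SYN_5_017	SYN_7_016	SYN_2_059	SYN_2_015	SYN_4_057	SYN_3_062	SYN_1_043	SYN_6_048
SYNGO:0017	dispersed process 5 (synthetic)	SYN_2_003	SYN_2_048	SYN_7_025	SYN_2_036	SYN_3_028	SYN_4_012	SYN_8_019	SYN_2_053	SYN_6_005	SYN_1_077	SYN_3_022	SYN_6_003	SYN_2_024	SYN_4_041	SYN_3_035	SYN_2_029	SYN_1_017	SYN_2_073	SYN_4_056	SYN_2_045	SYN_1_034	SYN_3_018	SYN_3_070	SYN_4_057	SYN_4_031	SYN_5_015	SYN_2_021	SYN_5_008	SYN_5_019	SYN_1_006	SYN_1_022	SYN_1_046	SYN_6_020	SYN_5_048	SYN_5_047	SYN_6_015	SYN_4_051	SYN_3_047	SYN_3_024	SYN_4_015
SYNGO:0018	dispersed process 6 (synthetic)	SYN_1_035	SYN_2_054	SYN_1_019	SYN_4_048	SYN_3_060	SYN_3_033	SYN_3_026	SYN_8_019	SYN_6_043	SYN_4_003	SYN_3_049	SYN_2_064	SYN_4_049	SYN_5_023	SYN_8_012	SYN_4_022	SYN_5_053	SYN_2_049	SYN_1_090	SYN_2_026	SYN_1_012	SYN_3_045	SYN_1_015	SYN_7_028	SYN_1_024	SYN_6_010	SYN_1_052	SYN_3_065	SYN_7_036	SYN_1_041	SYN_2_029	SYN_3_047	SYN_8_026	SYN_2_043	SYN_1_039	SYN_3_023	SYN_4_012	SYN_6_023	SYN_2_018	SYN_1_088
SYNGO:0019	dispersed process 7 (synthetic)	SYN_2_032	SYN_4_039	SYN_1_047	SYN_1_057	SYN_8_025	SYN_4_052	SYN_2_063	SYN_2_067	SYN_5_038	SYN_4_007	SYN_3_037	SYN_7_028	SYN_7_005	SYN_1_007	SYN_1_065	SYN_5_008	SYN_3_010	SYN_6_028	SYN_4_046	SYN_5_052	SYN_8_024	SYN_1_031	SYN_2_011	SYN_6_008	SYN_6_036	SYN_6_006	SYN_4_029	SYN_5_029	SYN_6_034	SYN_1_016	SYN_2_068	SYN_3_060	SYN_3_049	SYN_4_060	SYN_3_069	SYN_3_012	SYN_6_046	SYN_1_061	SYN_4_023	SYN_1_082
SYNGO:0020	dispersed process 8 (synthetic)	SYN_4_005	SYN_7_030	SYN_3_063	SYN_3_038	SYN_5_056	SYN_2_021	SYN_8_004	SYN_3_020	SYN_3_058	SYN_4_036	SYN_3_014	SYN_2_075	SYN_3_068	SYN_4_056	SYN_1_063	SYN_1_065	SYN_4_050	SYN_3_019	SYN_1_076	SYN_2_017	SYN_8_019	SYN_5_024	SYN_2_009	SYN_8_009	SYN_4_041	SYN_8_018	SYN_8_008	SYN_6_050	SYN_5_001	SYN_3_030	SYN_2_038	SYN_3_029	SYN_2_022	SYN_5_025	SYN_5_044	SYN_4_054	SYN_4_010	SYN_3_002	SYN_4_016	SYN_2_003
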