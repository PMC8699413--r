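#chrom	start	end	label	kind	genes
chr4	17200000	20577989	4q31.3_amplification1	amplification	SYN_4_036,SYN_4_037,SYN_4_038,SYN_4_039,SYN_4_040,SYN_4_041
chr4	23800000	27570444	4q12.1_amplification2	amplification	SYN_4_049,SYN_4_050,SYN_4_051,SYN_4_052,SYN_4_053,SYN_4_054,SYN_4_055
chr8	3500000	6426372	8q21.2_amplification3	amplification	SYN_8_008,SYN_8_009,SYN_8_010,SYN_8_011,SYN_8_012,SYN_8_013
chr6	13800000	17601508	6q21.3_amplification4	amplification	SYN_6_029,SYN_6_030,SYN_6_031,SYN_6_032,SYN_6_033,SYN_6_034,SYN_6_035,SYN_6_036
chr3	27000000	30115928	3q23.2_amplification5	amplification	SYN_3_055,SYN_3_056,SYN_3_057,SYN_3_058,SYN_3_059,SYN_3_060,SYN_3_061
chr3	7400000	10104148	3q23.3_amplification6	amplification	SYN_3_016,SYN_3_017,SYN_3_018,SYN_3_019,SYN_3_020,SYN_3_021
chr8	8200000	12181275	8q13.2_amplification7	amplification	SYN_8_018,SYN_8_019,SYN_8_020,SYN_8_021,SYN_8_022,SYN_8_023,SYN_8_024,SYN_8_025
chr4	2700000	4714415	4q13.2_amplification8	amplification	SYN_4_007,SYN_4_008,SYN_4_009,SYN_4_010
chr4	2600000	4733889	4q13.2_amplification9	amplification	SYN_4_006,SYN_4_007,SYN_4_008,SYN_4_009,SYN_4_010
chr7	4700000	8223877	7q22.2_amplification10	amplification	SYN_7_011,SYN_7_012,SYN_7_013,SYN_7_014,SYN_7_015,SYN_7_016,SYN_7_017
chr1	26400000	29906663	1q21.1_amplification11	amplification	SYN_1_054,SYN_1_055,SYN_1_056,SYN_1_057,SYN_1_058,SYN_1_059,SYN_1_060
chr8	11100000	13885829	8q33.2_amplification12	amplification	SYN_8_023,SYN_8_024,SYN_8_025,SYN_8_026,SYN_8_027,SYN_8_028
chr1	20600000	23561351	1q23.2_amplification13	amplification	SYN_1_042,SYN_1_043,SYN_1_044,SYN_1_045,SYN_1_046,SYN_1_047
chr4	18800000	21078169	4q32.3_amplification14	amplification	SYN_4_039,SYN_4_040,SYN_4_041,SYN_4_042
chr1	2200000	5305690	1q23.2_amplification15	amplification	SYN_1_006,SYN_1_007,SYN_1_008,SYN_1_009,SYN_1_010,SYN_1_011
chr3	22400000	24635410	3q31.3_amplification16	amplification	SYN_3_046,SYN_3_047,SYN_3_048,SYN_3_049,SYN_3_050
chr3	19200000	22092548	3q11.3_amplification17	amplification	SYN_3_040,SYN_3_041,SYN_3_042,SYN_3_043,SYN_3_044
chr6	17200000	19778625	6q22.2_amplification18	amplification	SYN_6_036,SYN_6_037,SYN_6_038,SYN_6_039,SYN_6_040
chr6	1300000	3537206	6q32.3_amplification19	amplification	SYN_6_004,SYN_6_005,SYN_6_006,SYN_6_007
chr1	28200000	31180818	1q23.2_amplification20	amplification	SYN_1_058,SYN_1_059,SYN_1_060,SYN_1_061,SYN_1_062,SYN_1_063
chr6	2700000	6132295	6q33.1_amplification21	amplification	SYN_6_007,SYN_6_008,SYN_6_009,SYN_6_010,SYN_6_011,SYN_6_012,SYN_6_013
chr8	5600000	7757809	8q32.2_amplification22	amplification	SYN_8_012,SYN_8_013,SYN_8_014,SYN_8_015,SYN_8_016
chr6	21500000	23818595	6q21.2_amplification23	amplification	SYN_6_044,SYN_6_045,SYN_6_046,SYN_6_047,SYN_6_048
chr5	23000000	26439295	5p23.3_deletion1	deletion	SYN_5_047,SYN_5_048,SYN_5_049,SYN_5_050,SYN_5_051,SYN_5_052,SYN_5_053
chr8	2500000	4504576	8p11.3_deletion2	deletion	SYN_8_006,SYN_8_007,SYN_8_008,SYN_8_009
chr1	3100000	6641301	1p13.1_deletion3	deletion	SYN_1_007,SYN_1_008,SYN_1_009,SYN_1_010,SYN_1_011,SYN_1_012,SYN_1_013,SYN_1_014
chr7	4800000	8452739	7p32.1_deletion4	deletion	SYN_7_011,SYN_7_012,SYN_7_013,SYN_7_014,SYN_7_015,SYN_7_016,SYN_7_017
chr5	10400000	13414437	5p33.1_deletion5	deletion	SYN_5_022,SYN_5_023,SYN_5_024,SYN_5_025,SYN_5_026,SYN_5_027
chr6	15300000	17976997	6p33.1_deletion6	deletion	SYN_6_032,SYN_6_033,SYN_6_034,SYN_6_035,SYN_6_036
chr7	2500000	5811414	7p11.2_deletion7	deletion	SYN_7_006,SYN_7_007,SYN_7_008,SYN_7_009,SYN_7_010,SYN_7_011,SYN_7_012
chr3	6200000	8441205	3p12.3_deletion8	deletion	SYN_3_014,SYN_3_015,SYN_3_016,SYN_3_017
chr5	8500000	10995326	5p23.3_deletion9	deletion	SYN_5_018,SYN_5_019,SYN_5_020,SYN_5_021,SYN_5_022
chr8	8000000	10979382	8p21.1_deletion10	deletion	SYN_8_017,SYN_8_018,SYN_8_019,SYN_8_020,SYN_8_021,SYN_8_022
chr8	2400000	5421538	8p22.1_deletion11	deletion	SYN_8_006,SYN_8_007,SYN_8_008,SYN_8_009,SYN_8_010,SYN_8_011
chr8	11100000	13651477	8p11.1_deletion12	deletion	SYN_8_023,SYN_8_024,SYN_8_025,SYN_8_026,SYN_8_027,SYN_8_028
chr4	20900000	24364815	4p21.1_deletion13	deletion	SYN_4_043,SYN_4_044,SYN_4_045,SYN_4_046,SYN_4_047,SYN_4_048,SYN_4_049
chr4	2500000	4927563	4p31.2_deletion14	deletion	SYN_4_006,SYN_4_007,SYN_4_008,SYN_4_009,SYN_4_010
chr4	8700000	12322460	4p32.3_deletion15	deletion	SYN_4_019,SYN_4_020,SYN_4_021,SYN_4_022,SYN_4_023,SYN_4_024,SYN_4_025
chr6	20800000	23174564	6p12.3_deletion16	deletion	SYN_6_043,SYN_6_044,SYN_6_045,SYN_6_046,SYN_6_047
chr3	10600000	13596007	3p23.2_deletion17	deletion	SYN_3_022,SYN_3_023,SYN_3_024,SYN_3_025,SYN_3_026,SYN_3_027
chr2	14600000	17447278	2p13.3_deletion18	deletion	SYN_2_030,SYN_2_031,SYN_2_032,SYN_2_033,SYN_2_034,SYN_2_035
chr8	3800000	6922203	8p12.3_deletion19	deletion	SYN_8_009,SYN_8_010,SYN_8_011,SYN_8_012,SYN_8_013,SYN_8_014
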