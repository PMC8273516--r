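gene	base_mean	log2_fold_change	fold_change	p_value	p_adjusted
C2	18052.368	4.944	30.785	0	0
Gpt2	35274.299	5.798	55.648	0	0
Amy1	3372.108	6.032	65.415	0	0
Bhmt	20021.646	9.792	886.725	0	0
Hsd17b3	18581.423	9.798	890.151	1.74E-281	1.39E-278
Aqp2	2981.622	7.231	150.243	4.42E-245	2.15E-242
Prps2	4552.373	3.749	13.443	2.18E-209	8.13E-207
Ces1d	11984.246	5.741	53.465	2.83E-205	9.87E-203
Glb1l2	4513.008	7.003	128.231	2.53E-199	8.47E-197
Lgals3bp	20133.117	6.373	82.884	1.14E-198	3.73E-196
Serpina3c	3338.273	4.255	19.093	1.48E-188	4.40E-186
Gpd1	3897.125	6.797	111.175	1.39E-179	3.79E-177
Stxbp3a	4243.740	3.010	8.055	3.20E-162	6.75E-160
Klf15	2928.645	3.176	9.037	9.87E-156	1.69E-153
Figf	3068.672	4.574	23.812	7.10E-154	1.18E-151
Sdsl	1122.063	4.313	19.877	2.78E-150	4.37E-148
Acox3	8397.935	3.121	8.700	4.46E-131	5.19E-129
Snx10	2540.155	6.134	70.221	1.75E-126	1.90E-124
Il17rb	1513.902	3.448	10.909	3.59E-122	3.74E-120
Kcnk1	2467.408	3.389	10.473	3.32E-114	3.04E-112
Sult1e1	2878.772	10.672	1631.859	1.02E-108	8.80E-107
Vcam1	46596.091	5.777	54.822	3.45E-107	2.87E-105
Slc7a11	4286.318	5.998	63.903	1.12E-104	8.95E-103
Serpina3n	2168.867	10.261	1227.344	6.47E-87	3.75E-85
Hsd3b6	32836.588	11.130	2240.546	8.96E-78	4.48E-76
Klk1b24	3178.152	11.822	3621.798	1.09E-75	5.12E-74
Gm11744	1030.205	3.358	10.252	2.68E-74	1.21E-72
Hpgd	1067.820	4.030	16.341	2.07E-61	6.54E-60
Rhbg	2880.708	12.255	4888.469	2.48E-60	7.62E-59
Serpina3g	462.145	5.205	36.876	1.89E-58	5.51E-57
Lbp	3087.023	8.037	262.650	9.19E-54	2.39E-52
Adhfe1	1625.652	2.181	4.535	1.71E-49	3.93E-48
Spon1	8151.291	9.477	712.435	4.49E-47	9.60E-46
Paqr6	391.005	5.686	51.499	6.54E-47	1.39E-45
Dcxr	1123.719	3.278	9.699	8.51E-46	1.77E-44
Nat8	724.703	4.189	18.234	7.05E-42	1.28E-40
Klk1b21	5523.987	11.869	3739.926	2.96E-40	5.07E-39
Rarres1	2641.251	8.946	493.252	2.68E-39	4.42E-38
Retsat	14825.614	3.468	11.067	9.21E-37	1.40E-35
Bpifb5	1962.336	4.132	17.531	1.77E-35	2.60E-34
Cml1	533.487	2.338	5.057	2.78E-34	3.89E-33
Adck3	7476.290	2.174	4.512	3.28E-32	4.23E-31
Lrg1	1040.072	11.788	3535.456	5.26E-30	6.29E-29
Cml5	687.203	3.956	15.522	5.53E-29	6.33E-28
Eppin	471.833	12.500	5793.895	1.31E-25	1.33E-24
Klk1b27	3989.849	13.693	13241.245	3.32E-25	3.31E-24
Espn	1912.055	1.994	3.983	5.15E-23	4.63E-22
C1rl	902.205	2.248	4.750	7.72E-22	6.55E-21
Asgr1	79.190	6.078	67.570	3.07E-20	2.39E-19
Serpina5	22933.474	1.330	2.514	0.004923864	0.008634922
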