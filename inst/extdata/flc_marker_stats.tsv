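gene	base_mean	log2_fold_change	fold_change	p_value	p_adjusted
Gsg1l	6453.385	-5.109	0.029	2.69E-295	2.54E-292
Crhr1	3886.902	-10.022	0.001	4.24E-191	1.31E-188
Cyp26b1	23010.196	-6.389	0.012	1.96E-109	1.70E-107
Pcsk6	2696.835	-4.599	0.041	1.38E-56	3.84E-55
Ren1	24383.988	-5.091	0.029	1.11E-29	1.31E-28
Vsnl1	168.482	-10.669	0.001	1.54E-17	1.02E-16
Ppp2r5b	8530.843	-1.116	0.461	1.18E-15	6.91E-15
Nppc	306.989	-3.352	0.098	2.17E-14	1.17E-13
Cdon	28637.299	-2.341	0.197	1.88E-05	4.58E-05
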