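g1_0001	g2_0001	62.4	128	48	0	1	128	1	128	1.051e-13	202.5
g1_0002	g2_0002	89.7	144	15	0	1	144	1	144	6.127e-14	197.5
g1_0003	g2_0003	94.9	232	12	0	1	232	1	232	5.899e-19	238.2
g1_0004	g2_0004	66.8	153	51	0	1	153	1	153	4.940e-26	304.0
g1_0005	g2_0005	81.4	225	42	0	1	225	1	225	3.947e-36	430.5
g1_0006	g2_0006	80.7	201	39	0	1	201	1	201	6.077e-29	350.1
g1_0007	g2_0007	90.3	128	12	0	1	128	1	128	3.254e-23	297.7
g1_0008	g2_0008	88.5	207	24	0	1	207	1	207	3.314e-44	522.3
g1_0009	g2_0009	77.9	126	28	0	1	126	1	126	5.266e-50	533.7
g1_0010	g2_0010	76.2	103	25	0	1	103	1	103	1.449e-42	468.3
g1_0011	g2_0011	87.4	150	19	0	1	150	1	150	3.952e-50	583.6
g1_0017	g2_0012	84.3	179	28	0	1	179	1	179	1.010e-36	404.4
g1_0018	g2_0013	64.3	168	60	0	1	168	1	168	8.136e-38	440.1
g1_0019	g2_0014	85.7	244	35	0	1	244	1	244	2.174e-29	366.7
g1_0020	g2_0015	91.8	189	15	0	1	189	1	189	7.849e-20	231.9
g1_0021	g2_0016	85.7	99	14	0	1	99	1	99	2.398e-37	448.1
g1_0027	g2_0017	81.9	168	30	0	1	168	1	168	1.845e-27	308.5
g1_0026	g2_0018	65.6	120	41	0	1	120	1	120	2.234e-17	227.4
g1_0025	g2_0019	77.8	210	47	0	1	210	1	210	3.878e-34	401.2
g1_0024	g2_0020	82.0	190	34	0	1	190	1	190	1.444e-32	364.7
g1_0023	g2_0021	94.9	193	10	0	1	193	1	193	3.968e-35	389.6
g1_0022	g2_0022	69.2	233	72	0	1	233	1	233	7.605e-14	197.9
g1_0028	g2_0023	66.0	106	36	0	1	106	1	106	6.293e-28	348.9
g1_0029	g2_0024	60.9	243	95	0	1	243	1	243	9.164e-39	445.8
g1_0030	g2_0025	61.0	188	73	0	1	188	1	188	8.232e-23	289.1
g1_0031	g2_0026	72.5	84	23	0	1	84	1	84	5.137e-22	290.0
g1_0032	g2_0030	87.8	241	29	0	1	241	1	241	7.237e-27	333.5
g1_0033	g2_0031	66.0	171	58	0	1	171	1	171	4.056e-30	366.3
g1_0034	g2_0032	78.1	183	40	0	1	183	1	183	3.335e-47	526.3
g1_0035	g2_0033	62.5	82	31	0	1	82	1	82	2.386e-17	223.8
g1_0004	g2_0027	91.2	153	13	0	1	153	1	153	3.245e-07	154.6
g1_0005	g2_0028	84.0	225	36	0	1	225	1	225	4.171e-06	135.8
g1_0006	g2_0029	66.7	201	67	0	1	201	1	201	1.818e-06	130.9
g1_0001	g2_0001	71.4	64	37	0	1	128	1	128	1.162e-08	136.6
g1_0002	g2_0002	80.5	72	28	0	1	144	1	144	7.032e-09	149.4
g1_0003	g2_0022	89.5	232	24	0	1	232	1	233	9.848e-08	110.9
g1_0020	g2_0031	81.3	171	32	0	1	189	1	171	1.469e-04	94.1
g1_0028	g2_0011	69.1	106	33	0	1	106	1	150	1.517e-08	127.3
g1_0018	g2_0031	66.1	168	57	0	1	168	1	171	2.835e+00	75.7
g1_0021	g2_0021	77.8	99	22	0	1	99	1	193	3.754e+00	55.1
g1_0029	g2_0026	91.3	84	7	0	1	243	1	84	1.843e+00	80.8
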