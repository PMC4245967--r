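g2_0001	g1_0001	92.1	128	10	0	1	128	1	128	9.341e-35	414.9
g2_0002	g1_0002	82.1	144	26	0	1	144	1	144	2.024e-45	506.2
g2_0003	g1_0003	91.4	232	20	0	1	232	1	232	3.969e-24	275.7
g2_0004	g1_0004	90.0	153	15	0	1	153	1	153	5.314e-17	238.1
g2_0005	g1_0005	70.1	225	67	0	1	225	1	225	5.445e-15	201.0
g2_0006	g1_0006	73.1	201	54	0	1	201	1	201	4.586e-21	270.4
g2_0007	g1_0007	87.0	128	17	0	1	128	1	128	2.620e-31	367.8
g2_0008	g1_0008	76.3	207	49	0	1	207	1	207	8.373e-40	457.7
g2_0009	g1_0009	61.0	126	49	0	1	126	1	126	9.455e-13	179.6
g2_0010	g1_0010	71.1	103	30	0	1	103	1	103	2.336e-37	418.7
g2_0011	g1_0011	73.7	150	39	0	1	150	1	150	5.312e-14	189.4
g2_0012	g1_0017	67.9	179	57	0	1	179	1	179	1.523e-20	284.1
g2_0013	g1_0018	68.5	168	53	0	1	168	1	168	1.140e-42	486.4
g2_0014	g1_0019	83.1	244	41	0	1	244	1	244	4.894e-43	465.2
g2_0015	g1_0020	75.5	189	46	0	1	189	1	189	2.349e-45	515.0
g2_0016	g1_0021	71.4	99	28	0	1	99	1	99	2.319e-39	458.6
g2_0017	g1_0027	76.0	168	40	0	1	168	1	168	6.339e-30	367.9
g2_0018	g1_0026	66.2	120	41	0	1	120	1	120	2.915e-45	501.8
g2_0019	g1_0025	63.6	210	76	0	1	210	1	210	4.407e-22	294.4
g2_0020	g1_0024	64.1	190	68	0	1	190	1	190	3.732e-23	293.4
g2_0021	g1_0023	70.7	193	57	0	1	193	1	193	3.243e-44	486.3
g2_0022	g1_0022	91.2	233	21	0	1	233	1	233	2.207e-36	410.8
g2_0023	g1_0028	80.0	106	21	0	1	106	1	106	2.639e-34	414.4
g2_0024	g1_0029	93.4	243	16	0	1	243	1	243	8.426e-23	298.8
g2_0025	g1_0030	71.7	188	53	0	1	188	1	188	5.025e-39	465.2
g2_0026	g1_0031	85.7	84	12	0	1	84	1	84	1.218e-29	340.6
g2_0030	g1_0032	75.5	241	59	0	1	241	1	241	8.903e-19	246.7
g2_0031	g1_0033	63.5	171	62	0	1	171	1	171	1.535e-50	568.4
g2_0032	g1_0034	80.5	183	36	0	1	183	1	183	1.590e-22	305.2
g2_0033	g1_0035	82.6	82	14	0	1	82	1	82	5.108e-16	200.1
g2_0027	g1_0004	77.9	153	34	0	1	153	1	153	6.013e-07	114.8
g2_0028	g1_0005	65.8	225	77	0	1	225	1	225	6.812e-08	146.7
g2_0029	g1_0006	68.2	201	64	0	1	201	1	201	5.372e-07	114.2
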