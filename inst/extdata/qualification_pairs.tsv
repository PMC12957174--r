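compound	dose_mg	dataset	predicted_auc	observed_auc	predicted_cmax	observed_cmax	reported_mfe_auc	reported_mfe_cmax
DMT	50.25	in_house_oral	42.79	49.16	19.79	14.1	0.87	1.3
HRM	132.75	in_house_oral	59.51	38.49	7.92	10.9	1.54	0.72
FL	20	lit_B36	822.96	424.18	21.4	10.1	1.94	2
FL	20	lit_B37	822.96	502.7	21.4	14.4	1.6	1.4
FL	20	lit_B42	822.96	1070.12	21.4	19.6	0.76	1
FL	20	lit_B43	822.96	1132.69	21.4	23.5	0.72	0.9
FL	20	lit_B44	822.96	623.44	21.4	10.2	1.3	2
FL	20	lit_B41	822.96	531.03	21.4	12.9	1.5	1.6
FL	40	lit_B35	1695.59	1907.86	42.9	35.2	0.88	1.2
NFL	NA	lit_B35	6340.72	6049.23	21.6	22.3	1	0.9
FL	40	lit_B45	1695.59	2065.23	42.9	27.8	0.82	1.5
NFL	NA	lit_B45	6340.72	6516.29	21.6	19.4	0.97	1.1
FL	40	lit_B38	1695.59	2725.1	42.9	23	0.61	1.8
NFL	NA	lit_B38	6340.72	4236.43	21.6	12.39	1.4	1.7
FL	40	lit_B46	1695.59	2373	42.9	28.8	0.71	1.4
NFL	NA	lit_B46	6340.72	6511.9	21.6	15.28	0.97	1.4
PR	20	lit_B47	181.49	111.79	8.1	6.9	1.6	1.1
PR	20	lit_B39	181.49	105.74	8.1	7.1	1.7	1.1
PR	20	lit_B31a	181.49	206.59	8.1	6.2	0.87	1.3
PR	20	lit_B31b	181.49	141.06	8.1	6.2	1.2	1.3
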