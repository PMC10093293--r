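gene	name	donor	acceptor	status	section	tissue	rel_prop_pct	freq_pct	freq_count	n_group	ratio_pct
BRCA1	BRCA1_circRNA_20-18	20	18	known	top	normal	10.94	84.21	32	38	4.73
BRCA1	BRCA1_circRNA_20-18	20	18	known	top	tumor	11.18	92.22	83	90	2.57
BRCA1	BRCA1_circRNA_7-6	7	6	known	top	normal	10.83	89.47	34	38	4.68
BRCA1	BRCA1_circRNA_7-6	7	6	known	top	tumor	7.93	87.78	79	90	1.82
BRCA1	BRCA1_circRNA_17-15	17	15	known	top	normal	10.31	92.11	35	38	4.46
BRCA1	BRCA1_circRNA_17-15	17	15	known	top	tumor	9.49	92.22	83	90	2.18
BRCA1	BRCA1_circRNA_19-18	19	18	known	top	normal	7.19	78.95	30	38	3.11
BRCA1	BRCA1_circRNA_19-18	19	18	known	top	tumor	5.8	84.44	76	90	1.33
BRCA1	BRCA1_circRNA_3-2	3	2	known	top	normal	5.42	44.74	17	38	2.34
BRCA1	BRCA1_circRNA_3-2	3	2	known	top	tumor	2.17	46.67	42	90	0.5
BRCA1	BRCA1_circRNA_10-2	10	2	known	top	normal	5	68.42	26	38	2.16
BRCA1	BRCA1_circRNA_10-2	10	2	known	top	tumor	3.78	72.22	65	90	0.87
BRCA1	BRCA1_circRNA_22-20	22	20	known	top	normal	3.65	50	19	38	1.58
BRCA1	BRCA1_circRNA_22-20	22	20	known	top	tumor	4.81	87.78	79	90	1.11
BRCA1	BRCA1_circRNA_10-6	10	6	known	top	normal	3.33	44.74	17	38	1.44
BRCA1	BRCA1_circRNA_10-6	10	6	known	top	tumor	2.66	63.33	57	90	0.61
BRCA1	BRCA1_circRNA_12-11	12	11	known	top	normal	3.33	55.26	21	38	1.44
BRCA1	BRCA1_circRNA_12-11	12	11	known	top	tumor	5.25	84.44	76	90	1.21
BRCA1	BRCA1_circRNA_23-18	23	18	known	top	normal	3.33	55.26	21	38	1.44
BRCA1	BRCA1_circRNA_23-18	23	18	known	top	tumor	5.15	81.11	73	90	1.18
BRCA1	BRCA1_circRNA_19-15	19	15	known	top	normal	3.23	52.63	20	38	1.4
BRCA1	BRCA1_circRNA_19-15	19	15	known	top	tumor	2.59	72.22	65	90	0.6
BRCA1	BRCA1_circRNA_8-6	8	6	known	top	normal	2.81	55.26	21	38	1.22
BRCA1	BRCA1_circRNA_8-6	8	6	known	top	tumor	2.08	56.67	51	90	0.48
BRCA1	BRCA1_circRNA_23-20	23	20	known	top	normal	2.71	42.11	16	38	1.17
BRCA1	BRCA1_circRNA_23-20	23	20	known	top	tumor	5.51	81.11	73	90	1.27
BRCA1	BRCA1_circRNA_21-18	21	18	known	top	normal	2.4	34.21	13	38	1.04
BRCA1	BRCA1_circRNA_21-18	21	18	known	top	tumor	2.68	63.33	57	90	0.62
BRCA1	BRCA1_circRNA_8-3	8	3	known	top	normal	2.08	42.11	16	38	0.9
BRCA1	BRCA1_circRNA_8-3	8	3	known	top	tumor	2.91	76.67	69	90	0.67
BRCA1	BRCA1_circRNA_5q-3	5q	3	novel	top	normal	1.67	13.16	5	38	0.72
BRCA1	BRCA1_circRNA_5q-3	5q	3	novel	top	tumor	0.71	22.22	20	90	0.16
BRCA1	BRCA1_circRNA_22-18	22	18	known	top	normal	1.56	31.58	12	38	0.68
BRCA1	BRCA1_circRNA_22-18	22	18	known	top	tumor	2.37	61.11	55	90	0.54
BRCA1	BRCA1_circRNA_23-15	23	15	known	top	normal	1.46	28.95	11	38	0.63
BRCA1	BRCA1_circRNA_23-15	23	15	known	top	tumor	1.24	43.33	39	90	0.28
BRCA1	BRCA1_circRNA_7-5	7	5	known	top	normal	1.35	28.95	11	38	0.59
BRCA1	BRCA1_circRNA_7-5	7	5	known	top	tumor	1.69	41.11	37	90	0.39
BRCA1	BRCA1_circRNA_20-15	20	15	known	top	normal	1.15	18.42	7	38	0.5
BRCA1	BRCA1_circRNA_20-15	20	15	known	top	tumor	1.75	55.56	50	90	0.4
BRCA1	BRCA1_circRNA_22-15	22	15	known	top	normal	1.04	26.32	10	38	0.45
BRCA1	BRCA1_circRNA_22-15	22	15	known	top	tumor	1.69	57.78	52	90	0.39
BRCA2	BRCA2_circRNA_7-3	7	3	known	top	normal	22.34	50	19	38	2.76
BRCA2	BRCA2_circRNA_7-3	7	3	known	top	tumor	26.13	76.67	69	90	1.48
BRCA2	BRCA2_circRNA_7-4	7	4	known	top	normal	19.68	55.26	21	38	2.43
BRCA2	BRCA2_circRNA_7-4	7	4	known	top	tumor	21.18	76.67	69	90	1.2
BRCA2	BRCA2_circRNA_18-17	18	17	known	top	normal	12.23	44.74	17	38	1.51
BRCA2	BRCA2_circRNA_18-17	18	17	known	top	tumor	12.61	61.11	55	90	0.71
BRCA2	BRCA2_circRNA_7-5	7	5	novel	top	normal	6.91	21.05	8	38	0.85
BRCA2	BRCA2_circRNA_7-5	7	5	novel	top	tumor	5.97	48.89	44	90	0.34
BRCA2	BRCA2_circRNA_9-9	9	9	novel	top	normal	4.79	21.05	8	38	0.59
BRCA2	BRCA2_circRNA_9-9	9	9	novel	top	tumor	2.1	24.44	22	90	0.12
BRCA2	BRCA2_circRNA_26-13	26	13	novel	top	normal	4.26	21.05	8	38	0.53
BRCA2	BRCA2_circRNA_26-13	26	13	novel	top	tumor	0.67	8.89	8	90	0.04
BRCA2	BRCA2_circRNA_21-20	21	20	known	top	normal	3.72	7.89	3	38	0.46
BRCA2	BRCA2_circRNA_21-20	21	20	known	top	tumor	1.51	18.89	17	90	0.09
BRCA2	BRCA2_circRNA_13-11	13	11	known	top	normal	3.19	13.16	5	38	0.39
BRCA2	BRCA2_circRNA_13-11	13	11	known	top	tumor	7.39	47.78	43	90	0.42
BRCA2	BRCA2_circRNA_4-3	4	3	known	top	normal	3.19	13.16	5	38	0.39
BRCA2	BRCA2_circRNA_4-3	4	3	known	top	tumor	3.61	32.22	29	90	0.2
BRCA2	BRCA2_circRNA_14-13	14	13	known	top	normal	2.66	13.16	5	38	0.33
BRCA2	BRCA2_circRNA_14-13	14	13	known	top	tumor	1.43	14.44	13	90	0.08
BRCA2	BRCA2_circRNA_10-4	10	4	known	top	normal	2.13	7.89	3	38	0.26
BRCA2	BRCA2_circRNA_10-4	10	4	known	top	tumor	1.01	10	9	90	0.06
BRCA2	BRCA2_circRNA_13-12	13	12	novel	top	normal	2.13	5.26	2	38	0.26
BRCA2	BRCA2_circRNA_13-12	13	12	novel	top	tumor	0.76	10	9	90	0.04
BRCA2	BRCA2_circRNA_6q-2	6q	2	novel	top	normal	2.13	10.53	4	38	0.26
BRCA2	BRCA2_circRNA_6q-2	6q	2	novel	top	tumor	0.76	10	9	90	0.04
BRCA2	BRCA2_circRNA_10-5	10	5	known	top	normal	1.6	7.89	3	38	0.2
BRCA2	BRCA2_circRNA_10-5	10	5	known	top	tumor	0.67	7.78	7	90	0.04
BRCA2	BRCA2_circRNA_10-8	10	8	known	top	normal	1.6	7.89	3	38	0.2
BRCA2	BRCA2_circRNA_10-8	10	8	known	top	tumor	1.43	17.78	16	90	0.08
BRCA2	BRCA2_circRNA_11-11	11	11	known	top	normal	1.6	7.89	3	38	0.2
BRCA2	BRCA2_circRNA_11-11	11	11	known	top	tumor	1.18	13.33	12	90	0.07
BRCA2	BRCA2_circRNA_10-3	10	3	known	top	normal	1.06	5.26	2	38	0.13
BRCA2	BRCA2_circRNA_10-3	10	3	known	top	tumor	1.01	12.22	11	90	0.06
BRCA2	BRCA2_circRNA_19-17	19	17	known	top	normal	1.06	5.26	2	38	0.13
BRCA2	BRCA2_circRNA_19-17	19	17	known	top	tumor	3.28	32.22	29	90	0.19
BRCA2	BRCA2_circRNA_24-19	24	19	known	top	normal	1.06	5.26	2	38	0.13
BRCA2	BRCA2_circRNA_24-19	24	19	known	top	tumor	2.1	20	18	90	0.12
BRCA2	BRCA2_circRNA_24-22	24	22	known	top	normal	1.06	5.26	2	38	0.13
BRCA2	BRCA2_circRNA_24-22	24	22	known	top	tumor	1.76	16.67	15	90	0.1
BRCA2	BRCA2_circRNA_24-21	24	21	known	top	normal	0.53	2.63	1	38	0.07
BRCA2	BRCA2_circRNA_24-21	24	21	known	top	tumor	2.44	28.89	26	90	0.14
BRCA1	BRCA1_circRNA_5q-3	5q	3	novel	novel	normal	1.67	13.16	5	38	0.72
BRCA1	BRCA1_circRNA_5q-3	5q	3	novel	novel	tumor	0.71	22.22	20	90	0.16
BRCA1	BRCA1_circRNA_23-8p	23	8p	novel	novel	normal	1.15	23.68	9	38	0.5
BRCA1	BRCA1_circRNA_23-8p	23	8p	novel	novel	tumor	0.76	40	36	90	0.18
BRCA1	BRCA1_circRNA_19-17	19	17	novel	novel	normal	1.04	21.05	8	38	0.45
BRCA1	BRCA1_circRNA_19-17	19	17	novel	novel	tumor	0.85	38.89	35	90	0.19
BRCA1	BRCA1_circRNA_18-2	18	2	novel	novel	normal	0.63	13.16	5	38	0.27
BRCA1	BRCA1_circRNA_18-2	18	2	novel	novel	tumor	0.25	14.44	13	90	0.06
BRCA1	BRCA1_circRNA_16-3	16	3	novel	novel	normal	0.52	13.16	5	38	0.23
BRCA1	BRCA1_circRNA_16-3	16	3	novel	novel	tumor	0.07	4.44	4	90	0.02
BRCA1	BRCA1_circRNA_23-22	23	22	novel	novel	normal	0.42	10.53	4	38	0.18
BRCA1	BRCA1_circRNA_23-22	23	22	novel	novel	tumor	0.1	6.67	6	90	0.02
BRCA1	BRCA1_circRNA_10-8	10	8	novel	novel	normal	0.31	7.89	3	38	0.14
BRCA1	BRCA1_circRNA_10-8	10	8	novel	novel	tumor	0.66	27.78	25	90	0.15
BRCA1	BRCA1_circRNA_20-20	20	20	novel	novel	normal	0.31	5.26	2	38	0.14
BRCA1	BRCA1_circRNA_20-20	20	20	novel	novel	tumor	0.41	11.11	10	90	0.09
BRCA1	BRCA1_circRNA_12-6	12	6	novel	novel	normal	0.1	2.63	1	38	0.05
BRCA1	BRCA1_circRNA_12-6	12	6	novel	novel	tumor	0.19	12.22	11	90	0.04
BRCA1	BRCA1_circRNA_21-20	21	20	novel	novel	normal	0.1	2.63	1	38	0.05
BRCA1	BRCA1_circRNA_21-20	21	20	novel	novel	tumor	0.1	6.67	6	90	0.02
BRCA2	BRCA2_circRNA_7-5	7	5	novel	novel	normal	6.91	21.05	8	38	0.85
BRCA2	BRCA2_circRNA_7-5	7	5	novel	novel	tumor	5.97	48.89	44	90	0.34
BRCA2	BRCA2_circRNA_9-9	9	9	novel	novel	normal	4.79	21.05	8	38	0.59
BRCA2	BRCA2_circRNA_9-9	9	9	novel	novel	tumor	2.1	24.44	22	90	0.12
BRCA2	BRCA2_circRNA_26-13	26	13	novel	novel	normal	4.26	21.05	8	38	0.53
BRCA2	BRCA2_circRNA_26-13	26	13	novel	novel	tumor	0.67	8.89	8	90	0.04
BRCA2	BRCA2_circRNA_13-12	13	12	novel	novel	normal	2.13	5.26	2	38	0.26
BRCA2	BRCA2_circRNA_13-12	13	12	novel	novel	tumor	0.76	10	9	90	0.04
BRCA2	BRCA2_circRNA_6q-2	6q	2	novel	novel	normal	2.13	10.53	4	38	0.26
BRCA2	BRCA2_circRNA_6q-2	6q	2	novel	novel	tumor	0.76	10	9	90	0.04
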