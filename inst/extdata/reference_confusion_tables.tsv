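tf	split	set	sens	spec	acc	mcc	tn	tp	fp	fn	all
TF0	1	A	0.6526	0.6875	0.6702	0.3404	62	66	30	33	191
TF0	1	P	0.6744	0.7944	0.7409	0.473	58	85	22	28	193
TF0	1	C	0.663	0.8061	0.7368	0.4749	61	79	19	31	190
TF0	1	V	0.6239	0.7407	0.6737	0.3613	68	60	21	41	190
TF0	2	A	0.8229	0.7604	0.7917	0.5845	79	73	23	17	192
TF0	2	P	0.7755	0.7957	0.7853	0.571	76	74	19	22	191
TF0	2	C	0.7727	0.7864	0.7801	0.5583	68	81	22	20	191
TF0	2	V	0.79	0.7333	0.7632	0.5245	79	66	24	21	190
TF0	3	A	0.7579	0.8144	0.7865	0.5734	72	79	18	23	192
TF0	3	P	0.7364	0.7317	0.7344	0.4643	81	60	22	29	192
TF0	3	C	0.734	0.6875	0.7105	0.4219	69	66	30	25	190
TF0	3	V	0.7711	0.8224	0.8	0.5935	64	88	19	19	190
TF0	4	A	0.7708	0.8105	0.7906	0.5817	74	77	18	22	191
TF0	4	P	0.6346	0.8023	0.7105	0.4385	66	69	17	38	190
TF0	4	C	0.6907	0.6915	0.6911	0.3822	67	65	29	30	191
TF0	4	V	0.6941	0.7103	0.7031	0.4025	59	76	31	26	192
TF0	5	A	0.8125	0.766	0.7895	0.5792	78	72	22	18	190
TF0	5	P	0.7157	0.8778	0.7917	0.597	73	79	11	29	192
TF0	5	C	0.5275	0.7374	0.6368	0.2713	48	73	26	43	190
TF0	5	V	0.6452	0.8889	0.7708	0.5529	60	88	11	33	192
TF0	6	A	0.8	0.7684	0.7842	0.5687	76	73	22	19	190
TF0	6	P	0.7976	0.7593	0.776	0.5528	67	82	26	17	192
TF0	6	C	0.7667	0.72	0.7421	0.4861	69	72	28	21	190
TF0	6	V	0.8053	0.6835	0.7552	0.4919	91	54	25	22	192
TF0	7	A	0.7604	0.7708	0.7656	0.5313	73	74	22	23	192
TF0	7	P	0.8023	0.6442	0.7158	0.4476	69	67	37	17	190
TF0	7	C	0.6374	0.44	0.534	0.0788	58	44	56	33	191
TF0	7	V	0.6055	0.5854	0.5969	0.1892	66	48	34	43	191
TF0	8	A	0.7474	0.7732	0.7604	0.5208	71	75	22	24	192
TF0	8	P	0.7473	0.7778	0.7632	0.5253	68	77	22	23	190
TF0	8	C	0.5729	0.7684	0.6702	0.3479	55	73	22	41	191
TF0	8	V	0.68	0.7582	0.7173	0.4385	68	69	22	32	191
TF0	9	A	0.7128	0.7188	0.7158	0.4315	67	69	27	27	190
TF0	9	P	0.7723	0.7419	0.7577	0.5145	78	69	24	23	194
TF0	9	C	0.5612	0.5217	0.5421	0.083	55	48	44	43	190
TF0	9	V	0.5281	0.6238	0.5789	0.1524	47	63	38	42	190
TF0	10	A	0.8105	0.8387	0.8245	0.6493	77	78	15	18	188
TF0	10	P	0.8481	0.8716	0.8617	0.7173	67	95	14	12	188
TF0	10	C	0.68	0.7553	0.7165	0.4359	68	71	23	32	194
TF0	10	V	0.713	0.7558	0.732	0.4658	77	65	21	31	194
TF1	1	A	0.6421	0.6458	0.644	0.2879	61	62	34	34	191
TF1	1	P	0.6279	0.6542	0.6425	0.2809	54	70	37	32	193
TF1	1	C	0.9239	0.8776	0.9	0.8012	85	86	12	7	190
TF1	1	V	0.8349	0.8765	0.8526	0.705	91	71	10	18	190
TF1	2	A	0.6875	0.6875	0.6875	0.375	66	66	30	30	192
TF1	2	P	0.7245	0.7634	0.7435	0.4879	71	71	22	27	191
TF1	2	C	0.9205	0.8738	0.8953	0.7919	81	90	13	7	191
TF1	2	V	0.9	0.8	0.8526	0.7057	90	72	18	10	190
TF1	3	A	0.6211	0.732	0.6771	0.3553	59	71	26	36	192
TF1	3	P	0.6273	0.7073	0.6615	0.3312	69	58	24	41	192
TF1	3	C	0.9149	0.8646	0.8895	0.7801	86	83	13	8	190
TF1	3	V	0.9277	0.8411	0.8789	0.7627	77	90	17	6	190
TF1	4	A	0.6771	0.7263	0.7016	0.4038	65	69	26	31	191
TF1	4	P	0.5769	0.7907	0.6737	0.372	60	68	18	44	190
TF1	4	C	0.9072	0.8511	0.8796	0.7599	88	80	14	9	191
TF1	4	V	0.8706	0.9065	0.8906	0.7781	74	97	10	11	192
TF1	5	A	0.7292	0.7447	0.7368	0.4738	70	70	24	26	190
TF1	5	P	0.6569	0.7778	0.7135	0.4357	67	70	20	35	192
TF1	5	C	0.7692	0.7677	0.7684	0.5366	70	76	23	21	190
TF1	5	V	0.8495	0.8889	0.8698	0.7394	79	88	11	14	192
TF1	6	A	0.7053	0.7368	0.7211	0.4423	67	70	25	28	190
TF1	6	P	0.6905	0.7222	0.7083	0.4109	58	78	30	26	192
TF1	6	C	0.8889	0.89	0.8895	0.7785	80	89	11	10	190
TF1	6	V	0.9115	0.8734	0.8958	0.7849	103	69	10	10	192
TF1	7	A	0.6354	0.6354	0.6354	0.2708	61	61	35	35	192
TF1	7	P	0.6395	0.6731	0.6579	0.3118	55	70	34	31	190
TF1	7	C	0.9011	0.89	0.8953	0.7905	82	89	11	9	191
TF1	7	V	0.8624	0.9024	0.8796	0.7589	94	74	8	15	191
TF1	8	A	0.6	0.732	0.6667	0.335	57	71	26	38	192
TF1	8	P	0.7473	0.7071	0.7263	0.454	68	70	29	23	190
TF1	8	C	0.9063	0.8842	0.8953	0.7907	87	84	11	9	191
TF1	8	V	0.95	0.8791	0.9162	0.8333	95	80	11	5	191
TF1	9	A	0.7021	0.6771	0.6895	0.3793	66	65	31	28	190
TF1	9	P	0.7426	0.6882	0.7165	0.4315	75	64	29	26	194
TF1	9	C	0.9388	0.7935	0.8684	0.7425	92	73	19	6	190
TF1	9	V	0.8427	0.8614	0.8526	0.7041	75	87	14	14	190
TF1	10	A	0.6632	0.7097	0.6862	0.3732	63	66	27	32	188
TF1	10	P	0.7468	0.6789	0.7074	0.4203	59	74	35	20	188
TF1	10	C	0.86	0.7979	0.8299	0.6598	86	75	19	14	194
TF1	10	V	0.8796	0.8953	0.8866	0.772	95	77	9	13	194
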