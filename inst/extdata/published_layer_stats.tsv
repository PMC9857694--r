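# Published per-layer statistics of four real multiplex datasets (as printed
# in the original data descriptions): drug trafficking (RCMP 'E' Division PTA),
# Sicilian Mafia (Mistretta/Batanesi investigation), London transport, and the
# C. elegans neural multiplex. density_e3 is the link density x 10^3.
dataset	layer	n_nodes	n_edges	density_e3	mean_degree	mean_cc_size	gcc_size	cov_cc_size
drug	co-offender	1645	1808	1.32	2.19	19.00	1024	5.71
drug	legitimate	1022	1041	2.00	2.04	10.99	462	4.43
drug	fco	560	597	3.81	2.13	14.36	150	2.24
drug	kinship	399	308	3.88	1.54	3.22	25	0.99
mafia	meeting	101	256	55.77	5.07	19.02	86	1.76
mafia	call	100	124	27.45	2.48	23.50	85	1.51
london	underground	260	225	6.68	1.73	5.65	98	2.48
london	overground	81	62	19.14	1.53	4.26	17	0.83
london	lightrail	44	34	35.94	1.55	4.00	8	0.54
celegans	electrical	242	450	15.43	3.72	80.67	237	1.37
celegans	chemical	260	869	25.81	6.68	130.00	258	0.98
celegans	polyadic	277	1666	43.58	12.03	277.00	277	0.00
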