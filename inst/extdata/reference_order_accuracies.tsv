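# published per-order accuracies (%) on the 3,137-compound benchmark, by class and overall
class_code	order1	order2	order3	order4	order5	order6	order7	order8	order9	order10	order11
1	80.96	8.38	5.08	1.78	1.02	1.27	0.25	1.02	0.00	0.25	0.00
2	31.67	30.00	18.33	7.50	4.17	3.33	0.00	3.33	0.00	0.83	0.83
3	73.89	6.27	6.27	4.44	1.57	2.61	2.35	0.52	0.52	1.31	0.26
4	65.15	11.36	6.82	5.30	3.03	1.52	2.27	0.00	4.55	0.00	0.00
5	61.70	19.88	10.97	5.38	1.04	0.83	0.21	0.00	0.00	0.00	0.00
6	29.87	27.27	11.69	11.69	5.19	5.19	3.90	3.25	1.95	0.00	0.00
7	20.93	25.58	11.63	9.30	6.98	4.65	2.33	4.65	0.00	2.33	11.63
8	61.17	17.15	9.39	4.21	3.24	2.91	0.97	0.32	0.32	0.32	0.00
9	74.35	8.42	4.01	3.41	1.20	1.20	2.20	2.40	1.00	1.20	0.60
10	68.98	8.67	4.62	3.66	5.01	4.24	1.54	1.54	0.77	0.58	0.39
11	78.77	8.42	5.09	2.81	2.63	1.40	0.35	0.35	0.18	0.00	0.00
Overall	77.97	14.19	8.07	4.88	2.93	2.55	1.43	1.28	0.70	0.57	0.38
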