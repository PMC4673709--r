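population	generation	cnv_type	chromosome_class	n_sampled	n_positive	freq_printed	copy_sw	copy_qpcr	copy_oacgh	parseable	freq_discrepant	note
16B	80	duplication	autosome	19	0	0.00	1.00	NA	NA	TRUE	FALSE	NA
16B	140	duplication	autosome	47	0	0.00	1.00	0.86	NA	TRUE	FALSE	NA
16B	200	duplication	autosome	43	28	0.41	1.41	1.02	1.19	TRUE	FALSE	NA
16E	80	duplication	autosome	30	1	0.02	1.02	1.08	NA	TRUE	FALSE	NA
16E	140	duplication	autosome	30	25	0.59	1.59	1.58	NA	TRUE	FALSE	NA
16E	200	duplication	autosome	18	18	1.00	2.00	2.39	2.08	TRUE	FALSE	NA
66E	140	duplication	autosome	27	10	0.20	1.20	1.23	NA	TRUE	TRUE	printed frequency 0.20; the Hardy-Weinberg estimate from 10/27 is 0.21
66E	200	duplication	autosome	28	22	0.54	1.54	1.67	1.33	TRUE	FALSE	NA
16A	140	deletion	X	30	30	1.00	0.00	0.00	NA	TRUE	FALSE	NA
16A	200	deletion	X	27	27	1.00	0.00	0.00	0.05	TRUE	FALSE	NA
16D	80	deletion	autosome	18	15	0.64	0.36	0.22	NA	TRUE	TRUE	printed frequency 0.64; the Hardy-Weinberg estimate from 15/18 is 0.59
16D	140	deletion	autosome	18	28	1.00	0.00	NA	NA	FALSE	FALSE	positives exceed sampled as printed; row excluded from analyses
16D	200	deletion	autosome	29	29	1.00	0.00	0.000738	0.05	TRUE	FALSE	NA
66B	80	deletion	X	32	0	0.00	1.00	0.73	NA	TRUE	FALSE	NA
66B	140	deletion	X	15	9	0.60	0.40	0.40	NA	TRUE	FALSE	NA
66B	200	deletion	X	28	28	1.00	0.00	0.0000269	0.04	TRUE	FALSE	NA
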