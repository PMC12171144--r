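chrom	start_mb	end_mb	pct
18	34.60	35.22	3.41
1	95.05	95.90	3.02
5	66.72	67.21	2.30
4	71.07	72.11	2.29
12	15.05	15.49	2.08
12	42.95	43.49	1.77
4	110.35	110.80	1.69
3	79.33	80.65	1.44
1	94.24	95.04	1.36
14	10.43	10.64	1.27
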