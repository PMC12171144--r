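chrom	start_mb	end_mb	pct
14	22.90	23.31	3.55
5	65.97	66.93	3.33
18	32.19	32.54	3.21
13	41.40	41.97	3.09
2	104.16	104.55	2.96
18	34.95	35.60	2.93
2	104.58	105.27	2.87
11	5.55	5.92	2.17
1	155.72	156.03	2.09
6	2.32	2.80	1.94
14	23.33	23.89	1.61
5	15.53	15.88	1.46
29	48.74	50.54	1.35
11	100.94	101.52	1.32
9	49.80	50.31	1.30
18	35.62	36.07	1.20
11	4.85	5.21	1.19
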