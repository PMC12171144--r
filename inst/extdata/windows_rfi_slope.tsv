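chrom	start_mb	end_mb	pct
4	70.83	71.85	6.89
14	24.39	24.91	3.60
5	66.51	67.03	3.51
21	7.35	8.15	3.26
2	104.16	104.55	2.89
14	22.99	23.45	2.04
2	104.65	105.41	1.65
7	16.07	16.44	1.56
14	24.91	25.43	1.49
14	22.61	22.99	1.45
11	74.02	74.67	1.31
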