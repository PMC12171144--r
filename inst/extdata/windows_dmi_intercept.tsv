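chrom	start_mb	end_mb	pct
6	37.15	37.95	4.29
14	22.90	23.31	4.14
1	95.09	95.95	3.66
18	34.83	35.42	3.64
21	68.47	68.77	3.15
6	36.02	36.57	2.66
29	46.18	47.10	2.52
8	67.24	67.72	2.42
29	48.54	50.15	2.40
4	70.88	71.88	2.21
20	9.15	9.83	2.04
14	23.33	23.89	1.70
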