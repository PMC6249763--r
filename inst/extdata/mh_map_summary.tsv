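lg	n_markers	length_cm	max_gap_cm
1	117	107.2	5.3
2	182	96.9	5.4
3	124	102.8	4.3
4	107	83.0	6.5
5	149	101.8	3.1
6	214	162.9	7.4
7	160	109.2	12.3
8	148	113.5	14.3
9	212	122.0	2.4
10	201	123.0	7.6
11	111	92.7	3.1
12	122	83.2	3.1
13	182	101.0	4.3
14	127	115.0	6.4
15	156	104.0	8.0
16	117	122.4	15.5
17	177	105.8	4.6
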