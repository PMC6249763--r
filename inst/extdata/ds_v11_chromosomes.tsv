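chrom	n_scaffolds	scaffold_bases	chrom_len
1	38	17741026	17744726
2	46	21235622	21240122
3	54	26905313	26910613
4	57	22557600	22563200
5	60	26919162	26925062
6	42	20808669	20812769
7	51	23073416	23078416
8	39	17213204	17217004
9	48	22543132	22547832
10	64	26037640	26043940
11	75	31663329	31670729
12	47	20526746	20531346
13	42	19240341	19244441
14	60	21933695	21939595
15	71	39101076	39108076
16	47	20394842	20399442
17	57	22680450	22686050
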