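partition	n_markers	n_scaffolds	with_1_marker	with_2_markers	with_3_markers	with_4plus_markers	total_bases
anchored	7757	898	73	104	93	628	400575263
oriented	7455	793	0	96	89	608	378731939
unanchored	106	1284	16	9	2	9	107975332
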