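map	n_markers	total_bases
MH	2606	351322567
YM	2489	353618398
BD	3143	336225218
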