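group	class	mean_ms	sd_ms
patient	A	70.07	21.14
patient	B	65.38	10.52
patient	C	62.30	10.03
patient	D	59.40	8.80
control	A	73.78	15.65
control	B	70.83	13.07
control	C	69.58	9.55
control	D	67.16	16.13
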