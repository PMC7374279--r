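symbol	chrom	start_bp	end_bp
PPARA	22	46594280	46631277
PPARD	6	35342558	35428191
PPARG	3	12287485	12434356
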