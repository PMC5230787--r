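feature	sensitive	resistant
n_genes	102	137
not_listed	28	32
listed	73	105
single_or_first	61	59
avg_utr_length	81	121
distal	12	46
intergenic_lt15	13	39
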