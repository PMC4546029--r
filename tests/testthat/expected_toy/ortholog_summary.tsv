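stat	n
n_pairs	1
n_distinct_a	1
n_distinct_b	1
n_same_class	1
n_unpaired_a	10
n_unpaired_b	0
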