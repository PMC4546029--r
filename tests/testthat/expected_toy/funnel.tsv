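stage	n
input	51
after_haplotype	50
after_gap	49
after_mismatch	48
after_numt	47
unspliced_ests	47
clusters	11
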