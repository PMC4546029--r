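cluster_a	cluster_b	detected_by	same_class
uc00005	uc00001	both	TRUE
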