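cluster_id	class	refseq_tss	orientation	rel_orientation	has_TSS_state	has_T_state	rnaseq_supported
uc00001	UT	TRUE	none	NA	FALSE	TRUE	TRUE
uc00002	5R	TRUE	none	NA	FALSE	FALSE	TRUE
uc00003	5PIN	FALSE	none	NA	TRUE	FALSE	TRUE
uc00004	TIN	FALSE	none	NA	FALSE	FALSE	FALSE
uc00005	TEX	FALSE	reverse	antisense	FALSE	TRUE	TRUE
uc00006	rI	FALSE	reverse	antisense	FALSE	FALSE	TRUE
uc00007	3PIN	FALSE	none	NA	TRUE	FALSE	TRUE
uc00008	3R	FALSE	forward	sense	FALSE	TRUE	TRUE
uc00009	DT	FALSE	forward	sense	FALSE	TRUE	TRUE
uc00010	NO_CLASS	FALSE	forward	antisense	FALSE	FALSE	TRUE
uc00011	IGR	FALSE	bidirectional	NA	TRUE	TRUE	TRUE
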