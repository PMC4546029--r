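chr1	12000	12200	uc00001	6	.
chr1	14920	15080	uc00002	3	.
chr1	15297	15457	uc00003	6	.
chr1	15557	15857	uc00004	5	.
chr1	16437	16587	uc00005	3	.
chr1	16673	17740	uc00006	4	.
chr1	19128	19288	uc00007	3	.
chr1	19498	19658	uc00008	3	.
chr1	22378	22578	uc00009	6	.
chr1	32612	33188	uc00010	3	.
chr1	46074	46274	uc00011	5	.
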