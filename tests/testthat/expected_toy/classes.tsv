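cluster_id	chrom	start	end	n_members	class	genes
uc00001	chr1	12000	12200	6	UT	g001
uc00002	chr1	14920	15080	3	5R	g001
uc00003	chr1	15297	15457	6	5PIN	g001
uc00004	chr1	15557	15857	5	TIN	g001
uc00005	chr1	16437	16587	3	TEX	g001
uc00006	chr1	16673	17740	4	rI	g001
uc00007	chr1	19128	19288	3	3PIN	g001
uc00008	chr1	19498	19658	3	3R	g001
uc00009	chr1	22378	22578	6	DT	g001
uc00010	chr1	32612	33188	3	NO_CLASS	g002
uc00011	chr1	46074	46274	5	IGR	
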