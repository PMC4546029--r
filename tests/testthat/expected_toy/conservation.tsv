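set	mean_score	n
TEX	0.396408666666667	1
TIN	0.0957076666666667	1
5PIN	0.213009375	1
3PIN	0.202525	1
rI	0.12478725398313	1
5R	0.263925	1
3R	0.252975	1
UT	0.10546	1
DT	0.094615	1
IGR	0.096769	1
NO_CLASS	0.29768125	1
AVG	0.184618196231646	10
bg_exons	0.393573354525965	8
bg_introns	0.104001007154458	6
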