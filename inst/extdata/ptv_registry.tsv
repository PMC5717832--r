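gene	cdna	protein	cases	early_onset	controls	exac_af	dbsnp	acmg_class
GCK	c.871A>T	p.K291*	1	1	0	NA	rs193922335	5
GCK	c.1340_1368del	p.R447fs	1	1	0	NA	NA	4
GCK	c.863+1G>T	p.?	1	0	0	NA	NA	4
HNF1A	c.994delG	p.E332fs	1	1	0	NA	NA	4
HNF1A	c.955+1G>T	p.?	1	1	0	NA	NA	4
HNF1A	c.1730_1733dupACCT	p.Q579fs	1	0	0	NA	NA	4
HNF1B	c.1005dupC	p.H336fs	1	1	0	NA	NA	4
PPARG	c.465delC	p.H155fs	1	0	0	NA	NA	4
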