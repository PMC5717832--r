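gene	cdna	protein	polyphen2	sift	mutationtaster	cadd	case_ages	control_carriers	prior_mody	exac_af	dbsnp	acmg_class
GCK	c.484G>A	p.G162S	probably_damaging	tolerated	disease_causing	26.5	13	0	1 family	NA	NA	3
GCK	c.952G>A	p.G318R	possibly_damaging	deleterious	disease_causing	27.2	14	0	4 families	NA	NA	4
GCK	c.617C>T	p.T206M	probably_damaging	deleterious	disease_causing	33	19	0	13 families	NA	NA	4
GCK	c.238G>A	p.G80S	probably_damaging	deleterious	disease_causing	32	24	0	2 families	NA	rs193922317	4
GCK	c.1349C>T	p.A450V	probably_damaging	deleterious	disease_causing	29.7	27	0	NA	NA	NA	3
GCK	c.911T>C	p.L304P	probably_damaging	tolerated	disease_causing	24.6	28	0	3 families	NA	NA	4
GCK	c.559G>T	p.D187Y	probably_damaging	deleterious	disease_causing	33	28	0	3 families	NA	NA	4
GCK	c.214G>A	p.G72R	probably_damaging	deleterious	disease_causing	34	29	0	18 families	NA	rs193922289	5
GCK	c.118G>A	p.E40K	probably_damaging	deleterious	disease_causing	33	30	0	5 families	NA	NA	4
GCK	c.562G>A	p.A188T	probably_damaging	deleterious	disease_causing	35	30	0	22 families	0.0001	rs751279776	4
GCK	c.640T>G	p.Y214D	probably_damaging	deleterious	disease_causing	27.2	33	0	NA	NA	NA	3
GCK	c.131G>A	p.G44D	probably_damaging	deleterious	disease_causing	29	34	0	4 families	NA	rs193922279	4
GCK	c.572G>A	p.R191Q	probably_damaging	deleterious	disease_causing	35	37	0	9 families	NA	NA	4
GCK	c.787_801del	p.263_267del	NA	NA	NA	NA	39	0	NA	NA	NA	4
GCK	c.544G>A	p.V182M	probably_damaging	deleterious	disease_causing	34	41	0	12 families	NA	rs587780345	5
GCK	c.706G>A	p.E236K	possibly_damaging	deleterious	disease_causing	33	42	0	2 families	NA	rs587780347	4
GCK	c.394G>A	p.D132N	benign	tolerated	disease_causing	23	56	0	1 family	0.000015	NA	3
GCK	c.757G>A	p.V253I	benign	tolerated	disease_causing	18.4	61	0	NA	0.00006	rs748964205	3
GCK	c.31G>A	p.A11T	benign	tolerated	polymorphism	12.8	32;45	0	NA	0.024	rs116093166	2
GCK	c.35A>G	p.K12R	benign	tolerated	polymorphism	16.8	NA	1	NA	0.000015	rs777958777	3
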