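variant_id	cdna	rel_expression_mean	rel_expression_sd	localization	rel_basal_mean	rel_basal_sd	rel_stimulated_mean	rel_stimulated_sd	f_index	predicted_severity
WT	.	100	.	Vesicles	100	.	171	14	1	Normal
Tyr106Phe	c.317A>T	111	10	Vesicles	95	10	153	14	0.94	Normal/mild
Gly172Ser	c.514G>A	113	6	Vesicles	100	4	183	13	1.35	Normal/mild
Cys205Phe	c.614G>T	50	11	ER/Vesicles	41	10	42	1	0	Severe
Asn415Thr	c.1244A>C	72	11	Vesicles	58	9	56	10	-0.02	Severe
Val643Gly	c.1928T>G	121	12	Vesicles	83	6	115	15	0.48	Moderate
Pro799Leu	c.2396C>T	43	5	ER/small vesicles	70	13	99	16	0.17	Moderate
Pro940Arg	c.2819C>G	100	18	Vesicles	100	7	170	20	1.01	Normal/mild
Lys1164Arg	c.3491A>G	115	23	Vesicles	93	4	155	30	0.9	Normal/mild
Val1433Ile	c.4297G>A	86	12	Vesicles	76	17	112	28	0.41	Moderate
Val2050Leu	c.6148G>C	107	13	Vesicles	98	10	157	3	0.92	Normal/mild
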