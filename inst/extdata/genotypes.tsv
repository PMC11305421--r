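patient_id	allele	variant_id	origin	stage	age_at_presentation	disease_duration
P1	1	Tyr106Phe	.	I	16	14
P1	2	Arg290Trp	.	I	16	14
P1	3	Thr959Ala	.	I	16	14
P2	1	Tyr106Phe	.	I	16	14
P2	2	Arg290Trp	.	I	16	14
P2	3	Thr959Ala	.	I	16	14
P3	1	Gly172Ser	maternal	.	31	.
P3	2	Val2050Leu	paternal	.	31	.
P4	1	Cys205Phe	.	I	36	25
P4	2	Gly1961Glu	.	I	36	25
P4	3	c.3523-9C>G	.	I	36	25
P5	1	Asn415Thr	.	IIIC	6	43
P5	2	c.5461-10T>C	.	IIIC	6	43
P5	3	Asn1868Ile	.	IIIC	6	43
P6	1	Val643Gly	.	II	60	2
P6	2	Cys2150Tyr	.	II	60	2
P7	1	Pro799Leu	.	IIIA	46	5
P7	2	Leu1580Ter	.	IIIA	46	5
P8	1	Pro940Arg	maternal	IIIB	10	38
P8	2	Glu1122Lys	maternal	IIIB	10	38
P8	3	c.161-23T>G	paternal	IIIB	10	38
P9	1	Lys1164Arg	maternal	IIIB	19	38
P9	2	c.769-784C>T	maternal	IIIB	19	38
P9	3	c.4540-2077C>T	paternal	IIIB	19	38
P10	1	Val1433Ile	.	.	60	.
P10	2	c.3607+771G>A	.	.	60	.
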