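variant_id	cdna	protein	revel	spliceai_max_delta	aux_splice_novel_site	gnomad_af	gnomad_homozygotes	reported_in_patient	hypomorphic_flag	localization	clinvar_same_residue	consequence	passthrough_codes
Tyr106Phe	c.317A>T	p.(Tyr106Phe)	0.261	0.01	FALSE	2e-5	0	TRUE	FALSE	vesicles	.	missense	.
Arg290Trp	c.868C>T	p.(Arg290Trp)	0.525	0.06	FALSE	2e-5	0	TRUE	FALSE	.	[{"protein_change":"Arg290Gln","classification":"P","reported_in_abca4rd_patient":true,"revel":0.5}]	missense	PM3:very_strong
Thr959Ala	c.2875A>G	p.(Thr959Ala)	0.962	0	FALSE	2e-5	0	TRUE	FALSE	.	[{"protein_change":"Thr959Ile","classification":"LP","reported_in_abca4rd_patient":true,"revel":0.9}]	missense	PM3:moderate
Gly172Ser	c.514G>A	p.(Gly172Ser)	0.496	0.03	FALSE	2e-5	0	TRUE	FALSE	vesicles	.	missense	PM3:strong;BP2:supporting;BP5:supporting
Val2050Leu	c.6148G>C	p.(Val2050Leu)	0.795	0.01	FALSE	0.012	60	TRUE	FALSE	vesicles	.	missense	BP2:supporting;BP5:supporting
Cys205Phe	c.614G>T	p.(Cys205Phe)	0.967	0	FALSE	2e-5	0	TRUE	FALSE	mixed	[{"protein_change":"Cys205Arg","classification":"P","reported_in_abca4rd_patient":true,"revel":0.9}]	missense	PM3:moderate;PP5:supporting
Gly1961Glu	c.5882G>A	p.(Gly1961Glu)	0.76	0.01	FALSE	0.004	25	TRUE	FALSE	.	[{"protein_change":"Gly1961Arg","classification":"P","reported_in_abca4rd_patient":true,"revel":0.85}]	missense	PM3:very_strong;PP5:supporting
c.3523-9C>G	c.3523-9C>G	.	.	0.02	FALSE	2e-5	0	TRUE	FALSE	.	.	splice_region	BP2:supporting
Asn415Thr	c.1244A>C	p.(Asn415Thr)	0.817	0	FALSE	2e-5	0	TRUE	FALSE	vesicles	.	missense	PM3:supporting
c.5461-10T>C	c.5461-10T>C	p.Thr1821Aspfs*6	.	0.07	FALSE	2e-5	0	TRUE	FALSE	.	.	splice_region	PM3:very_strong;PS3:strong;PP5:supporting
Asn1868Ile	c.5603A>T	p.(Asn1868Ile)	0.402	0	FALSE	0.04	400	TRUE	TRUE	.	.	missense	.
Val643Gly	c.1928T>G	p.(Val643Gly)	0.944	0.01	FALSE	0.002	6	TRUE	FALSE	vesicles	.	missense	.
Cys2150Tyr	c.6449G>A	p.(Cys2150Tyr)	0.923	0.02	FALSE	2e-5	0	TRUE	FALSE	.	.	missense	PM3:very_strong;PP5:supporting
Pro799Leu	c.2396C>T	p.(Pro799Leu)	0.542	0.01	FALSE	2e-5	0	TRUE	FALSE	er	.	missense	PM3:supporting
Leu1580Ter	c.4734del	p.(Leu1580*)	.	0.01	FALSE	2e-5	0	TRUE	FALSE	.	.	nonsense	PVS1:very_strong;PM3:moderate
Pro940Arg	c.2819C>G	p.(Pro940Arg)	0.273	0	FALSE	2e-5	0	TRUE	FALSE	vesicles	.	missense	BP2:supporting
Glu1122Lys	c.3364G>A	p.(Glu1122Lys)	0.939	0.02	FALSE	2e-5	0	TRUE	FALSE	.	.	missense	PM3:very_strong;PP5:supporting
c.161-23T>G	c.161-23T>G	p.(Cys54=, Cys54Serfs*14)	.	0.02	FALSE	2e-5	0	TRUE	FALSE	.	.	intronic	PM3:strong;PS3:moderate
Lys1164Arg	c.3491A>G	p.(Lys1164Arg)	0.199	0.01	FALSE	2e-5	0	TRUE	FALSE	vesicles	.	missense	.
c.769-784C>T	c.769-784C>T	p.(Leu257=, Leu257Aspfs*3)	.	0.08	FALSE	2e-5	0	TRUE	FALSE	.	.	intronic	PS3:supporting;PM3:strong;BP2:supporting
c.4540-2077C>T	c.4540-2077C>T	.	.	0	TRUE	2e-5	0	TRUE	FALSE	.	.	intronic	.
Val1433Ile	c.4297G>A	p.(Val1433Ile)	0.605	0.1	FALSE	0.003	9	TRUE	FALSE	vesicles	.	missense	.
c.3607+771G>A	c.3607+771G>A	.	.	0	FALSE	2e-5	0	TRUE	FALSE	.	.	intronic	.
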