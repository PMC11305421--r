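patient_id	variant_id	cdna	protein	study_variant	revel	spliceai	subscores	classification
P1, P2	Tyr106Phe	c.317A>T	p.(Tyr106Phe)	TRUE	0.261	0.01	BS3_sup, BP4, PM2_sup	Likely benign
P1, P2	Arg290Trp	c.868C>T	p.(Arg290Trp)	FALSE	0.525	0.06	PM3_very strong, PM5, PM2_sup	Pathogenic
P1, P2	Thr959Ala	c.2875A>G	p.(Thr959Ala)	FALSE	0.962	0	PM3, PM5, PM2_sup, PP3	Likely pathogenic
P3	Gly172Ser	c.514G>A	p.(Gly172Ser)	TRUE	0.496	0.03	PM3_strong, PM2_sup, BS3_sup, BP2, BP5	VUS
P3	Val2050Leu	c.6148G>C	p.(Val2050Leu)	TRUE	0.795	0.01	BS3_sup, BP2, BP5, PP3	Likely benign
P4	Cys205Phe	c.614G>T	p.(Cys205Phe)	TRUE	0.967	0	PS3, PM2_sup, PM3, PM5, PP3, PP5	Pathogenic
P4	Gly1961Glu	c.5882G>A	p.(Gly1961Glu)	FALSE	0.76	0.01	PM3_very strong, PM5, PP3, PP5	Pathogenic
P4	c.3523-9C>G	c.3523-9C>G	.	FALSE	.	0.02	PM2_sup, BP2, BP4	Likely benign
P5	Asn415Thr	c.1244A>C	p.(Asn415Thr)	TRUE	0.817	0	PS3, PM2_sup, PM3_sup, PP3	Likely pathogenic
P5	c.5461-10T>C	c.5461-10T>C	p.Thr1821Aspfs*6	FALSE	.	0.07	PM3_very strong, PS3, PM2_sup, PP5	Pathogenic
P5	Asn1868Ile	c.5603A>T	p.(Asn1868Ile)	FALSE	0.402	0	Hypomorphic	NA
P6	Val643Gly	c.1928T>G	p.(Val643Gly)	TRUE	0.944	0.01	PS3, PP3	VUS
P6	Cys2150Tyr	c.6449G>A	p.(Cys2150Tyr)	FALSE	0.923	0.02	PM3_very strong, PM2_sup, PP3, PP5	Pathogenic
P7	Pro799Leu	c.2396C>T	p.(Pro799Leu)	TRUE	0.542	0.01	PS3, PM2_sup, PM3_sup	Likely pathogenic
P7	Leu1580Ter	c.4734del	p.(Leu1580*)	FALSE	.	0.01	PVS1, PM3, PM2_sup	Pathogenic
P8	Pro940Arg	c.2819C>G	p.(Pro940Arg)	TRUE	0.273	0	PM2_sup, BS3_sup, BP4, BP2	Likely benign
P8	Glu1122Lys	c.3364G>A	p.(Glu1122Lys)	FALSE	0.939	0.02	PM3_very strong, PM2_sup, PP3, PP5	Pathogenic
P8	c.161-23T>G	c.161-23T>G	p.(Cys54=, Cys54Serfs*14)	FALSE	.	0.02	PM3_strong, PS3_mod, PM2_sup	Likely pathogenic
P9	Lys1164Arg	c.3491A>G	p.(Lys1164Arg)	TRUE	0.199	0.01	PM2_sup, BS3_sup, BP4	Likely benign
P9	c.769-784C>T	c.769-784C>T	p.(Leu257=, Leu257Aspfs*3)	FALSE	.	0.08	PM2_sup, PS3_sup, PM3_strong, BP2	VUS
P9	c.4540-2077C>T	c.4540-2077C>T	.	FALSE	.	0	PM2_sup	VUS
P10	Val1433Ile	c.4297G>A	p.(Val1433Ile)	TRUE	0.605	0.1	PS3	VUS
P10	c.3607+771G>A	c.3607+771G>A	.	FALSE	.	0	PM2_sup, BP4	VUS
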