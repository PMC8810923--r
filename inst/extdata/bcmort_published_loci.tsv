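snp_id	gene	effect_allele	other_allele	beta_I	se_I	beta_P	se_P	beta_SH_published	se_SH_published	beta_DHO_published	se_DHO_published
rs370332736	NA	A	AACTT	0.05	0.03	0.15	0.03	0.17	0.03	0.16	0.03
rs35054928	FGFR2	G	GC	-0.27	0.02	0.03	0.02	-0.04	0.017	0.01	0.02
rs35850695	Tox3	A	G	0.23	0.02	0.01	0.02	0.07	0.018	0.02	0.02
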