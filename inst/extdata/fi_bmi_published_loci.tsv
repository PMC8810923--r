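snp_id	gene	effect_allele	other_allele	beta_I	se_I	beta_P	se_P	beta_SH_published	se_SH_published	beta_DHO_published	se_DHO_published
rs1260326	GCKR	T	C	-0.011	0.001	-0.023	0.004	-0.026	0.004	-0.023	0.004
rs1919128	C2orf16	A	G	0.009	0.001	0.022	0.004	0.025	0.004	0.023	0.004
rs3749147	GPN1	A	G	-0.009	0.002	-0.022	0.005	-0.025	0.004	-0.023	0.005
rs7607980	COBLL1	T	C	-0.015	0.003	0.030	0.006	0.025	0.006	0.028	0.006
rs1801282	PPARG	C	G	-0.017	0.003	0.025	0.004	0.019	0.005	0.023	0.005
rs1421085	FTO	T	C	-0.078	0.002	0.001	0.004	-0.024	0.004	-0.006	0.004
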