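# Five-day x three-replicate validation of AgNP particle mass concentration (C_m).
# mean/stdev in g per kg of sample; s_r, s_d, s_ip, u_t, u_r, u_d, U in % of the mean; U expanded with k=2.
sample	code	measurand	mean	stdev	s_r	s_d	s_ip	u_t	u_r	u_d	U	n	d
Aqueous dispersion of AgNP	NM-300K	C_m	44	4	9.6	6.4	12	2.9	5.6	6.4	18	3	1
E174 2-mm flakes	Ag-005	C_m	2.3	0.2	29	11	31	2.9	17	11	41	3	1
E174 8-cm leaves	Ag-008	C_m	1.9	0.2	19	6.3	20	2.9	11	6.3	26	3	1
Silver pearls containing E174	Ag-P-002	C_m	0.008	0.001	19	13	23	2.9	11	13	34	3	1
Silver-coated chocolates containing E174	Ag-P-003	C_m	0.010	0.001	23	9.0	25	2.9	14	9.0	33	3	1
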