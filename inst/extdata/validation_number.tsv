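# Five-day x three-replicate validation of AgNP particle number concentration (C_p).
# mean/stdev in particles per kg of sample; s_r, s_d, s_ip, u_t, u_r, u_d, U in % of the mean; U expanded with k=2.
sample	code	measurand	mean	stdev	s_r	s_d	s_ip	u_t	u_r	u_d	U	n	d
Aqueous dispersion of AgNP	NM-300K	C_p	1.7e18	0.2e18	7.8	8.9	12	3.3	4.5	8.9	21	3	1
E174 2-mm flakes	Ag-005	C_p	6.9e15	0.8e15	22	13	25	3.3	13	13	36	3	1
E174 8-cm leaves	Ag-008	C_p	1.2e16	0.06e16	17	6.6	18	3.3	9.9	6.6	25	3	1
Silver pearls containing E174	Ag-P-002	C_p	4.4e13	1.1e13	16	12	20	3.3	9.2	12	31	3	1
Silver-coated chocolates containing E174	Ag-P-003	C_p	4.2e13	1.1e13	19	20	27	3.3	11	20	45	3	1
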