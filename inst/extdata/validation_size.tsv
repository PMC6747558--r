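# Five-day x three-replicate validation of median AgNP size determination.
# mean/stdev in nm; s_r, s_d, s_ip, u_t, u_r, u_d, U in % of the mean; U expanded with k=2.
# n, d: replicates and days assumed for the routine-conditions budget of that row.
sample	code	measurand	mean	stdev	s_r	s_d	s_ip	u_t	u_r	u_d	U	n	d
Aqueous dispersion of AgNP	NM-300K	Feret-min	15.4	0.5	2.4	2.5	3.4	4.8	2.4	2.5	12	1	1
Aqueous dispersion of AgNP	NM-300K	ESD	15.3	0.4	0.9	2.8	3.0	6.0	0.5	2.8	13	3	1
E174 2-mm flakes	Ag-005	ESD	26.7	1.3	11	7.3	13	6.0	6.3	7.3	23	3	1
E174 8-cm leaves	Ag-008	ESD	18.7	1.5	4.2	7.8	8.9	6.0	2.4	7.8	20	3	1
Silver pearls containing E174	Ag-P-002	ESD	19.4	0.7	5.5	1.5	5.7	6.0	3.2	1.5	14	3	1
Silver-coated chocolates containing E174	Ag-P-003	ESD	22.5	1.2	6.2	3.4	7.1	6.0	3.6	3.4	16	3	1
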