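event_id	gene_symbol	event_class	region	delta_nt	psi_pdb_mean	psi_pdb_sd	psi_hd_mean	psi_hd_sd	n_pdb	n_hd	p_allPDB_vs_allHD
LGALS8.1	LGALS8	cassette_exon	coding	142	0.08	0.04	0.14	0.04	19	16	0.00001
USP4.1	USP4	cassette_exon	coding	141	0.20	0.04	0.27	0.06	19	16	0.0002
CASC4.1	CASC4	cassette_exon	coding	168	0.21	0.06	0.29	0.06	19	16	0.001
RHOT1.1	RHOT1	cassette_exon	coding	96	0.16	0.04	0.23	0.08	19	16	0.001
PIDD.1	PIDD	alt_3prime_site	coding	51	0.63	0.06	0.58	0.05	19	16	0.01
TBC1D25.1	TBC1D25	cassette_exon	utr5	155	0.63	0.05	0.68	0.06	19	16	0.03
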