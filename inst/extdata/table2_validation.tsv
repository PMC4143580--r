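event_id	gene_symbol	primer_fwd	primer_rev	allPDB_vs_allHD.p	allPDB_vs_allHD.q	allPDB_vs_HDwt.p	allPDB_vs_HDwt.q	PDBwt_vs_HDwt.p	PDBwt_vs_HDwt.q	PDBwt_vs_HDP392L.p	PDBwt_vs_HDP392L.q	PDBwt_vs_PDBP392L.p	PDBwt_vs_PDBP392L.q	HDwt_vs_HDP392L.p	HDwt_vs_HDP392L.q
LGALS8.1	LGALS8	ACACTCTGGGCATTTATGGC	TTTAACGACGACAGTTCGTCC	0.00001	0.0002	0.0005	0.009	0.0004	0.004	0.001	0.008	0.64	0.55	0.71	0.55
USP4.1	USP4	AGCTATTCAACATCCCTGCG	GGTGGCTCCTGACAATTATACG	0.0002	0.0012	0.0019	0.013	0.002	0.006	0.033	0.054	0.73	0.55	0.48	0.51
CASC4.1	CASC4	GAGGTGGTGATGCAGGGATGC	GATCCATTTGAAGCTCTCGTTCTTC	0.001	0.004	0.001	0.009	0.001	0.004	0.050	0.07	0.15	0.27	0.22	0.39
RHOT1.1	RHOT1	TCCACCACAAGCCTTCACTT	GTGCACATACAGCGTAACCG	0.001	0.004	0.018	0.061	0.021	0.042	0.003	0.0019	0.88	0.59	0.89	0.66
PIDD.1	PIDD	ATGTTCGAGGGCGAAGAGTT	CGCCACGGTAGAAGGACAC	0.01	0.03	0.03	0.08	0.03	0.04	0.03	0.05	0.68	0.55	0.62	0.51
LGALS9.1	LGALS9	GTGATGGTGAACGGGATCCT	GTTGGCAGGCCACACGCC	0.02	0.03	0.053	0.11	0.14	0.18	0.10	0.12	0.38	0.42	0.81	0.68
TBC1D25.1	TBC1D25	AATGTGAGAGCTTCTTGCCG	AGGATGGACTGTGTAAAGGGC	0.03	0.05	0.04	0.10	0.01	0.02	0.02	0.05	0.04	0.24	0.35	0.39
THAP1.1	THAP1	AGGACAAGCCCGTTTCTTTC	TCCAATAGCAGCATCAACCTG	0.04	0.09	0.01	0.051	0.01	0.04	0.43	0.44	0.53	0.49	0.27	0.39
ABTB1.1	ABTB1	GAGCAGCGAGACGTGGAG	GCTTGTAATCGCGTAGAGCC	0.09	0.33	0.01	0.057	0.02	0.08	0.56	0.44	0.12	0.27	0.08	0.39
WARS.1	WARS	AGCGTGACCAGTGGCCAC	GCCTTTTGCACTGCTTGTCT	0.28	0.39	0.51	0.67	0.84	0.85	0.48	0.44	0.15	0.27	0.50	0.55
PIDD.2	PIDD	CTGAGCTTGGACCTGTACCC	AGGCCACTCAGACCAGCG	0.23	0.39	0.42	0.65	0.47	0.59	0.73	0.47	0.03	0.24	0.27	0.39
METTL13.1	METTL13	CATGCGTGCGTTTGTCGT	ATGTCGATGTTCACTATATCCCG	0.42	0.56	0.78	0.87	0.50	0.50	0.01	0.05	0.11	0.27	0.29	0.39
L3MBTL.1	L3MBTL	CCAAGTGGACCATCGATGAG	AGCAAATGAGTGGGTAGAGAGC	0.34	0.56	0.22	0.43	0.24	0.49	1.00	0.56	0.82	0.59	0.22	0.39
BTC.1	BTC	ACCACCACACAATCAAAGCG	TTACGACGTTTCCGAAGAGG	0.41	0.56	0.57	0.70	0.80	0.79	0.75	0.47	0.19	0.29	0.51	0.51
NLRP12.1	NLRP12	TCAGTGTGAACCAGAGCCTG	CAGGTAAAGGTCGGTCAAGG	0.41	0.56	0.80	0.87	0.38	0.50	0.03	0.05	0.22	0.29	0.25	0.39
CASC4.2	CASC4	GCTCAAACTTGGACAGTGAACC	GCAGGATCCATTTGAAGCTC	0.66	0.92	0.42	0.65	0.24	0.48	0.87	0.52	0.37	0.42	0.21	0.39
ABI1.1	ABI1	AGTTCTGGATGATGTGGGCC	TGGCGGTTTCTGAGTAGGAGGA	0.85	0.94	0.46	0.65	0.37	0.50	0.52	0.44	0.48	0.49	0.20	0.39
RAB3IP.1	RAB3IP	TGGGATTACAACCTATCCGG	CCCTGCTGAATGTATCGAATG	0.89	0.94	0.44	0.65	0.50	0.53	0.44	0.44	0.98	0.63	0.24	0.39
PRMT2.1	PRMT2	GCTCCTGGAAAGGACCGTC	TTAGGCTCTGCCTCATAACTGC	0.85	0.97	0.93	0.87	0.93	0.85	0.70	0.47	NA	NA	0.28	0.39
BCL2L12.1	BCL2L12	TCCTAGCTGCCTTCCTTAG	GTATGGCTTCCTTCTCTGTC	0.87	0.92	0.86	0.87	0.48	0.61	0.58	0.44	0.14	0.27	0.95	0.68
BCL2L15.1	BCL2L15	TTGAGGAACAAACGGAATGC	AGCTAAGCTGGAATCCTGAGC	0.98	0.98	0.91	0.87	0.87	0.82	NA	NA	NA	NA	NA	NA
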