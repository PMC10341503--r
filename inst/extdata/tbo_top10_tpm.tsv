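# Ten most expressed genes of each of four Tuber borchii SP1 culture
# conditions (per-million values; union of the four top-10 lists, absence
# from a sample's top-10 encoded as 0). Partial matrix: read with
# unit = "per_million", partial = TRUE and use total = 1e6.
gene_id	WPG	WPGY	PDB	MPY
990338	59710.6	59732.8	0	0
1125059	37904.9	38565.1	13738.2	0
985714	19175.7	19689.8	0	0
986569	18513.8	18720.1	0	0
907400	15291.6	15059.6	12134	8022.94
1138063	12188.2	12331.1	18989.4	9857.26
1039918	11559.9	11506.3	0	0
1067414	9526.58	9622.65	20972.3	13726.7
961630	9394.31	9712.31	9060.03	0
1124376	9124.24	9300.14	10231.8	8576.88
1098806	0	0	16159.1	11293
957843	0	0	13582.2	19500.8
1103054	0	0	9425.23	0
981017	0	0	6404.74	0
892438	0	0	0	18481.5
987363	0	0	0	10269.6
1041746	0	0	0	9720.97
1127611	0	0	0	8393.75
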