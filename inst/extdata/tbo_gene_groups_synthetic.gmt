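glycolysis	glycolysis pathway gene models (synthetic placeholder members except listed ids)	1092436	957843	1079835	1133725	1077976	syn_glyc_01	syn_glyc_02	syn_glyc_03	syn_glyc_04	syn_glyc_05	syn_glyc_06	syn_glyc_07	syn_glyc_08	syn_glyc_09	syn_glyc_10	syn_glyc_11	syn_glyc_12	syn_glyc_13	syn_glyc_14	syn_glyc_15	syn_glyc_16	syn_glyc_17	syn_glyc_18	syn_glyc_19	syn_glyc_20	syn_glyc_21	syn_glyc_22	syn_glyc_23	syn_glyc_24	syn_glyc_25	syn_glyc_26	syn_glyc_27	syn_glyc_28	syn_glyc_29	syn_glyc_30	syn_glyc_31	syn_glyc_32	syn_glyc_33	syn_glyc_34	syn_glyc_35	syn_glyc_36	syn_glyc_37	syn_glyc_38
tca	TCA cycle genes (synthetic placeholder members)	syn_tca_01	syn_tca_02	syn_tca_03	syn_tca_04	syn_tca_05	syn_tca_06	syn_tca_07	syn_tca_08	syn_tca_09	syn_tca_10	syn_tca_11	syn_tca_12	syn_tca_13	syn_tca_14	syn_tca_15	syn_tca_16	syn_tca_17	syn_tca_18	syn_tca_19	syn_tca_20	syn_tca_21	syn_tca_22	syn_tca_23	syn_tca_24	syn_tca_25
etc	electron transport chain genes, two shared with tca (synthetic placeholder members)	syn_tca_24	syn_tca_25	syn_etc_01	syn_etc_02	syn_etc_03	syn_etc_04	syn_etc_05	syn_etc_06	syn_etc_07	syn_etc_08	syn_etc_09
glyoxylate	glyoxylate cycle: two isocitrate lyases and one malate synthase (synthetic placeholders)	syn_gox_il1	syn_gox_il2	syn_gox_ms1
aroma	aroma-related genes (synthetic placeholder members except 1133725)	1133725	syn_aro_01	syn_aro_02	syn_aro_03	syn_aro_04	syn_aro_05	syn_aro_06	syn_aro_07	syn_aro_08	syn_aro_09	syn_aro_10	syn_aro_11	syn_aro_12	syn_aro_13	syn_aro_14	syn_aro_15	syn_aro_16	syn_aro_17	syn_aro_18	syn_aro_19	syn_aro_20	syn_aro_21	syn_aro_22	syn_aro_23	syn_aro_24	syn_aro_25	syn_aro_26	syn_aro_27	syn_aro_28	syn_aro_29	syn_aro_30	syn_aro_31	syn_aro_32	syn_aro_33	syn_aro_34	syn_aro_35	syn_aro_36	syn_aro_37	syn_aro_38	syn_aro_39	syn_aro_40	syn_aro_41	syn_aro_42	syn_aro_43	syn_aro_44	syn_aro_45	syn_aro_46	syn_aro_47	syn_aro_48	syn_aro_49	syn_aro_50	syn_aro_51	syn_aro_52	syn_aro_53	syn_aro_54	syn_aro_55	syn_aro_56	syn_aro_57	syn_aro_58	syn_aro_59	syn_aro_60	syn_aro_61	syn_aro_62	syn_aro_63	syn_aro_64	syn_aro_65	syn_aro_66	syn_aro_67	syn_aro_68	syn_aro_69	syn_aro_70	syn_aro_71	syn_aro_72	syn_aro_73	syn_aro_74	syn_aro_75	syn_aro_76	syn_aro_77	syn_aro_78	syn_aro_79	syn_aro_80	syn_aro_81	syn_aro_82	syn_aro_83	syn_aro_84	syn_aro_85	syn_aro_86	syn_aro_87	syn_aro_88	syn_aro_89	syn_aro_90	syn_aro_91
nrps	NRPS cluster	1077522	1099828	1122331
pks	type I PKS cluster	962914
nrps_like_1	NRPS-like cluster 1 (synthetic split)	1126844	966209
nrps_like_2	NRPS-like cluster 2 (synthetic split)	1119995
nrps_like_3	NRPS-like cluster 3 (synthetic split)	1032817
pks_like_1	PKS-like cluster 1	1116892
pks_like_2	PKS-like cluster 2	1121687	970716	1076327	970641
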