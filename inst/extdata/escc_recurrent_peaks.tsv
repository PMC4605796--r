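cytoband	chromosome	start	end	direction	min_q	frequency_pct	n_genes	genes
11q13.2	chr11	69034285	69149286	amplification	1.58e-20	80.6	1	CCND1
8p11.23	chr8	39356625	39535683	amplification	6.02e-17	90.3	1	ANON_8P11.23_01
7p11.2	chr7	54816792	55162089	amplification	1.65e-07	61.3	1	EGFR
3q26.33	chr3	182878001	183294550	amplification	0.00098284	85.5	1	SOX2
3q13.2	chr3	113499996	114212594	amplification	0.023964	67.7	9	CD200,ATG3,ANON_3Q13.2_01,ANON_3Q13.2_02,ANON_3Q13.2_03,ANON_3Q13.2_04,ANON_3Q13.2_05,ANON_3Q13.2_06,ANON_3Q13.2_07
17q12	chr17	35017165	35202671	amplification	0.031192	58	10	ERBB2,GRB7,ANON_17Q12_01,ANON_17Q12_02,ANON_17Q12_03,ANON_17Q12_04,ANON_17Q12_05,ANON_17Q12_06,ANON_17Q12_07,ANON_17Q12_08
18q22.1	chr18	45971551	76117153	deletion	1.9e-06	71	93	BCL2,SMAD4,NFATC1,ANON_18Q22.1_01,ANON_18Q22.1_02,ANON_18Q22.1_03,ANON_18Q22.1_04,ANON_18Q22.1_05,ANON_18Q22.1_06,ANON_18Q22.1_07,ANON_18Q22.1_08,ANON_18Q22.1_09,ANON_18Q22.1_10,ANON_18Q22.1_11,ANON_18Q22.1_12,ANON_18Q22.1_13,ANON_18Q22.1_14,ANON_18Q22.1_15,ANON_18Q22.1_16,ANON_18Q22.1_17,ANON_18Q22.1_18,ANON_18Q22.1_19,ANON_18Q22.1_20,ANON_18Q22.1_21,ANON_18Q22.1_22,ANON_18Q22.1_23,ANON_18Q22.1_24,ANON_18Q22.1_25,ANON_18Q22.1_26,ANON_18Q22.1_27,ANON_18Q22.1_28,ANON_18Q22.1_29,ANON_18Q22.1_30,ANON_18Q22.1_31,ANON_18Q22.1_32,ANON_18Q22.1_33,ANON_18Q22.1_34,ANON_18Q22.1_35,ANON_18Q22.1_36,ANON_18Q22.1_37,ANON_18Q22.1_38,ANON_18Q22.1_39,ANON_18Q22.1_40,ANON_18Q22.1_41,ANON_18Q22.1_42,ANON_18Q22.1_43,ANON_18Q22.1_44,ANON_18Q22.1_45,ANON_18Q22.1_46,ANON_18Q22.1_47,ANON_18Q22.1_48,ANON_18Q22.1_49,ANON_18Q22.1_50,ANON_18Q22.1_51,ANON_18Q22.1_52,ANON_18Q22.1_53,ANON_18Q22.1_54,ANON_18Q22.1_55,ANON_18Q22.1_56,ANON_18Q22.1_57,ANON_18Q22.1_58,ANON_18Q22.1_59,ANON_18Q22.1_60,ANON_18Q22.1_61,ANON_18Q22.1_62,ANON_18Q22.1_63,ANON_18Q22.1_64,ANON_18Q22.1_65,ANON_18Q22.1_66,ANON_18Q22.1_67,ANON_18Q22.1_68,ANON_18Q22.1_69,ANON_18Q22.1_70,ANON_18Q22.1_71,ANON_18Q22.1_72,ANON_18Q22.1_73,ANON_18Q22.1_74,ANON_18Q22.1_75,ANON_18Q22.1_76,ANON_18Q22.1_77,ANON_18Q22.1_78,ANON_18Q22.1_79,ANON_18Q22.1_80,ANON_18Q22.1_81,ANON_18Q22.1_82,ANON_18Q22.1_83,ANON_18Q22.1_84,ANON_18Q22.1_85,ANON_18Q22.1_86,ANON_18Q22.1_87,ANON_18Q22.1_88,ANON_18Q22.1_89,ANON_18Q22.1_90
3p14.2	chr3	59007938	61527556	deletion	0.00073274	93.5	1	FHIT
3p24.1	chr3	30021139	31677792	deletion	0.0031654	91.9	3	TGFBR2,ANON_3P24.1_01,ANON_3P24.1_02
3p14.1	chr3	70098576	71732543	deletion	0.040761	91.9	1	FOXP1
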