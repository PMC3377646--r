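organism	locus_tag	gh_family	activity	is_pseudo	regulated
A_cellulolyticus	Acel_0614	GH5	endocellulase	FALSE	TRUE
A_cellulolyticus	Acel_0135	GH6	endocellulase	FALSE	TRUE
A_cellulolyticus	Acel_0970	GH9	endocellulase	FALSE	FALSE
A_cellulolyticus	Acel_0615	GH12	endocellulase	FALSE	TRUE
A_cellulolyticus	Acel_0619	GH12	endocellulase	FALSE	FALSE
A_cellulolyticus	Acel_0615	GH6	exocellulase	FALSE	TRUE
A_cellulolyticus	Acel_0617	GH48	exocellulase	FALSE	TRUE
A_cellulolyticus	Acel_1701	GH9	processive	FALSE	TRUE
A_robiniae	Actro_1189	GH5	endocellulase	FALSE	TRUE
A_robiniae	Actro_2709	GH5	endocellulase	FALSE	TRUE
A_robiniae	Actro_8514	GH5	endocellulase	FALSE	TRUE
A_robiniae	Actro_2135	GH6	endocellulase	FALSE	TRUE
A_robiniae	Actro_2190	GH6	endocellulase	FALSE	FALSE
A_robiniae	Actro_2697	GH6	endocellulase	FALSE	FALSE
A_robiniae	Actro_1734	GH9	endocellulase	FALSE	FALSE
A_robiniae	Actro_1655	GH12	endocellulase	FALSE	FALSE
A_robiniae	Actro_1922	GH12	endocellulase	FALSE	TRUE
A_robiniae	Actro_1014	GH51	endocellulase	FALSE	TRUE
A_robiniae	Actro_3019	GH51	endocellulase	FALSE	FALSE
A_robiniae	Actro_6327	GH51	endocellulase	FALSE	FALSE
A_robiniae	Actro_7002	GH51	endocellulase	FALSE	FALSE
A_robiniae	Actro_7965	GH51	endocellulase	FALSE	TRUE
A_robiniae	Actro_8127	GH51	endocellulase	FALSE	FALSE
A_robiniae	Actro_8126	GH6	exocellulase	FALSE	FALSE
A_robiniae	Actro_0272	GH48	exocellulase	FALSE	TRUE
A_robiniae	Actro_7971	GH48	exocellulase	FALSE	FALSE
A_robiniae	Actro_7966	GH9	processive	FALSE	TRUE
A_mirum	Amir_2781	GH5	endocellulase	FALSE	FALSE
A_mirum	Amir_3216	GH5	endocellulase	FALSE	TRUE
A_mirum	Amir_3335	GH5	endocellulase	FALSE	FALSE
A_mirum	Amir_2166	GH6	endocellulase	FALSE	TRUE
A_mirum	Amir_3215	GH6	endocellulase	FALSE	TRUE
A_mirum	Amir_5339	GH9	endocellulase	FALSE	TRUE
A_mirum	Amir_3027	GH12	endocellulase	FALSE	FALSE
A_mirum	Amir_3987	GH12	endocellulase	FALSE	FALSE
A_mirum	Amir_2048	GH51	endocellulase	FALSE	TRUE
A_mirum	Amir_2191	GH6	exocellulase	FALSE	TRUE
A_mirum	Amir_2167	GH48	exocellulase	FALSE	TRUE
C_acidiphila	Caci_4214	GH5	endocellulase	FALSE	TRUE
C_acidiphila	Caci_4876	GH5	endocellulase	FALSE	TRUE
C_acidiphila	Caci_4946	GH5	endocellulase	FALSE	TRUE
C_acidiphila	Caci_5006	GH5	endocellulase	FALSE	FALSE
C_acidiphila	Caci_3602	GH6	endocellulase	FALSE	TRUE
C_acidiphila	Caci_6555	GH6	endocellulase	FALSE	TRUE
C_acidiphila	Caci_3603	GH12	endocellulase	FALSE	TRUE
C_acidiphila	Caci_4157	GH51	endocellulase	FALSE	FALSE
C_acidiphila	Caci_4289	GH51	endocellulase	FALSE	FALSE
C_acidiphila	Caci_6262	GH51	endocellulase	FALSE	FALSE
C_acidiphila	Caci_6640	GH51	endocellulase	FALSE	TRUE
C_acidiphila	Caci_4881	GH6	exocellulase	FALSE	TRUE
C_acidiphila	Caci_6683	GH6	exocellulase	FALSE	FALSE
C_acidiphila	Caci_3604	GH48	exocellulase	FALSE	FALSE
C_acidiphila	Caci_0460	GH9	processive	FALSE	TRUE
C_flavigena	Cfla_1897	GH5	endocellulase	FALSE	FALSE
C_flavigena	Cfla_2912	GH6	endocellulase	FALSE	TRUE
C_flavigena	Cfla_2913	GH6	endocellulase	FALSE	TRUE
C_flavigena	Cfla_0139	GH9	endocellulase	FALSE	TRUE
C_flavigena	Cfla_1515	GH9	endocellulase	FALSE	TRUE
C_flavigena	Cfla_3031	GH9	endocellulase	FALSE	FALSE
C_flavigena	Cfla_3563	GH9	endocellulase	FALSE	TRUE
C_flavigena	Cfla_1896	GH6	exocellulase	FALSE	TRUE
C_flavigena	Cfla_3105	GH48	exocellulase	FALSE	TRUE
C_flavigena	Cfla_0016	GH9	processive	FALSE	TRUE
J_denitrificans	Jden_0734	GH5	endocellulase	FALSE	FALSE
J_denitrificans	Jden_0538	GH6	endocellulase	FALSE	FALSE
J_denitrificans	Jden_0735	GH6	exocellulase	FALSE	FALSE
J_denitrificans	Jden_1134	GH48	exocellulase	FALSE	FALSE
N_dassonvillei	Ndas_1368	GH5	endocellulase	FALSE	FALSE
N_dassonvillei	Ndas_4194	GH6	endocellulase	FALSE	TRUE
N_dassonvillei	Ndas_4558	GH9	endocellulase	FALSE	TRUE
N_dassonvillei	Ndas_2449	GH6	exocellulase	FALSE	TRUE
N_dassonvillei	Ndas_3519	GH6	exocellulase	FALSE	TRUE
N_dassonvillei	Ndas_2448	GH48	exocellulase	FALSE	TRUE
S_nassauensis	Snas_1941	GH5	endocellulase	FALSE	FALSE
S_nassauensis	Snas_6330	GH6	endocellulase	FALSE	TRUE
S_nassauensis	Snas_2947	GH6	exocellulase	FALSE	TRUE
S_roseum	Sros_3907	GH6	endocellulase	FALSE	FALSE
S_roseum	Sros_6407	GH6	endocellulase	FALSE	TRUE
S_roseum	Sros_1551	GH8	endocellulase	FALSE	FALSE
S_roseum	Sros_8280	GH9	endocellulase	FALSE	TRUE
S_roseum	Sros_6890	GH6	exocellulase	FALSE	TRUE
S_roseum	Sros_0936	GH48	exocellulase	FALSE	TRUE
S_roseum	Sros_0935	GH9	processive	FALSE	FALSE
T_fusca	Tfu_0901	GH5	endocellulase	FALSE	TRUE
T_fusca	Tfu_2712	GH5	endocellulase	FALSE	FALSE
T_fusca	Tfu_1074	GH6	endocellulase	FALSE	TRUE
T_fusca	Tfu_1627	GH9	endocellulase	FALSE	TRUE
T_fusca	Tfu_0620	GH6	exocellulase	FALSE	TRUE
T_fusca	Tfu_1959	GH48	exocellulase	FALSE	TRUE
T_fusca	Tfu_2176	GH9	processive	FALSE	TRUE
T_bispora	Tbis_2830	GH6	endocellulase	FALSE	TRUE
T_bispora	Tbis_0352	GH12	endocellulase	FALSE	FALSE
T_bispora	Tbis_2656	GH6	exocellulase	FALSE	TRUE
T_bispora	Tbis_2138	GH48	exocellulase	FALSE	TRUE
T_curvata	Tcur_1738	GH6	endocellulase	FALSE	TRUE
T_curvata	Tcur_4570	GH6	exocellulase	TRUE	FALSE
T_curvata	Tcur_4566	GH48	exocellulase	TRUE	FALSE
X_cellulosilytica	Xcel_0182	GH5	endocellulase	FALSE	FALSE
X_cellulosilytica	Xcel_0236	GH6	endocellulase	FALSE	TRUE
X_cellulosilytica	Xcel_3146	GH6	endocellulase	FALSE	FALSE
X_cellulosilytica	Xcel_1150	GH6	exocellulase	FALSE	FALSE
X_cellulosilytica	Xcel_1153	GH48	exocellulase	FALSE	FALSE
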