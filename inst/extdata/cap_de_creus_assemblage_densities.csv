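# Density (colonies m-2) of the three gorgonian species per benthic assemblage
# at Cap de Creus. total_* columns: mean +/- SD over all sampling units in the
# assemblage (occupied or not); patch_* columns: mean +/- SD over occupied
# units only. An empty patch_sd means a single occupied unit (SD undefined).
# zone: shallow or deep benthic assemblage.
species,assemblage,zone,total_density,total_sd,n_units,patch_density,patch_sd,n_occupied
P_clavata,vertical_coralligenous,shallow,0.423,1.562,376,3.698,3.063,43
P_clavata,platform_coralligenous,deep,1.000,2.945,118,4.370,4.871,27
E_singularis,photophilic_algae,shallow,0.323,1.840,93,2.000,4.318,15
E_singularis,precoralligenous,shallow,3.129,6.200,167,5.559,7.413,94
E_singularis,vertical_coralligenous,shallow,1.737,4.109,376,4.213,5.533,155
E_singularis,platform_coralligenous,deep,6.631,8.532,118,9.543,8.776,82
L_sarmentosa,photophilic_algae,shallow,0.005,0.052,93,0.500,,1
L_sarmentosa,precoralligenous,shallow,0.021,0.149,167,0.875,0.479,4
L_sarmentosa,vertical_coralligenous,shallow,0.013,0.109,376,0.714,0.393,7
L_sarmentosa,platform_coralligenous,deep,0.017,0.112,118,0.667,0.289,3
L_sarmentosa,littoral_sandy_mud,shallow,0.008,0.063,64,0.500,,1
L_sarmentosa,littoral_medium_coarse_sand,shallow,0.013,0.081,113,0.500,0.000,3
L_sarmentosa,detrital_littoral_sands,deep,0.015,0.105,423,0.591,0.302,11
L_sarmentosa,detrital_littoral_sandy_mud,deep,0.057,0.193,211,0.600,0.262,20
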