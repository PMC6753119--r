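# SYNTHETIC habitat-area table (not survey data): plausible hectares of
# suitable benthic assemblage per species at a Cap-de-Creus-like site, for
# exercising the upscaling stage. species_list is semicolon-separated.
assemblage,area_ha,zone,species_list
vertical_coralligenous,24.0,shallow,P_clavata;E_singularis;L_sarmentosa
platform_coralligenous,18.5,deep,P_clavata;E_singularis;L_sarmentosa
precoralligenous,42.0,shallow,E_singularis;L_sarmentosa
photophilic_algae,61.0,shallow,E_singularis;L_sarmentosa
littoral_sandy_mud,35.0,shallow,L_sarmentosa
littoral_medium_coarse_sand,54.0,shallow,L_sarmentosa
detrital_littoral_sands,120.0,deep,L_sarmentosa
detrital_littoral_sandy_mud,88.0,deep,L_sarmentosa
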