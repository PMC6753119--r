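# Reported per-compartment (species x depth zone) summaries for the 1.14 ha of
# ROV transects surveyed at Cap de Creus (NW Mediterranean), spring snapshot.
# Units: biomass g AFDM; daily ingestion/respiration g C d-1; spring flux g C;
# annual sink g C yr-1. These observed totals calibrate the effective rates.
species,zone,n_colonies,biomass_g_afdm,daily_ingestion_gC,daily_respiration_gC,spring_flux_gC,annual_sink_gC
P_clavata,shallow,269,1269.66,10.04,5.14,441.35,57.42
P_clavata,deep,366,1258.64,9.73,3.40,570.18,61.36
E_singularis,shallow,2229,1629.15,36.40,4.28,2890.24,322.77
E_singularis,deep,2162,627.37,7.80,0.85,625.99,236.60
L_sarmentosa,shallow,23,6.46,0.06,0.02,3.17,1.18
L_sarmentosa,deep,35,9.61,0.09,0.03,5.58,1.78
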