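# Reported per-species carbon sink rates over the suitable habitat of the
# whole Cap de Creus area, kg C per hectare per year. Used as inputs to the
# combined area-wide sequestration total (the per-assemblage suitable areas
# behind each value are not public).
species,sink_kgC_ha_yr
P_clavata,2.58
E_singularis,8.90
L_sarmentosa,0.02
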