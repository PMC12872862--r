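parameter,baseline_mean,followup_mean
stroke_work_mmHg_mL,13182,8902
potential_energy_mmHg_mL,11374,7118
end_systolic_elastance_mmHg_mL,2.36,2.22
arterial_elastance_mmHg_mL,2.65,2.22
ventriculo_arterial_coupling,1.17,1.01
esp_over_edv_mmHg_mL,1.24,1.10
pmax_over_edv_mmHg_mL,1.28,1.13
global_work_index_mmHg_pct,3208,2353
global_constructive_work_mmHg_pct,3549,2696
global_wasted_work_mmHg_pct,128,132
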