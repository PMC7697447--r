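record_id,source_ref,substance,cas,molecular_weight,physical_state,vapour_pressure_kpa,dustiness,proc,setting,conc_band,dur_band,duration_min,sampling_duration_min,location,general_ventilation,lev_present,lev_reported_effective,rpe,rpe_worn,measurement_inside_rpe,n,gm,gsd,units,notes
wex-1-isopropanol-printing,industrial printing survey (isopropanol),isopropanol,67-63-0,60.10,liquid,4.1,,10,industrial,>25%,>4 h,480,480,indoor,good,FALSE,,none,FALSE,,13,24.1,1.44,ppm,"13 samples, 320-572 min; GM 59.3 mg/m3 (24.1 ppm), GSD 1.44"
wex-2-sevoflurane-theatre,operating-theatre anaesthetic survey (sevoflurane),sevoflurane,28523-86-6,200.05,liquid,26,,2,professional,1-5%,1-4 h,120,360,indoor,good,TRUE,,none,FALSE,,42,0.2067627,2.0,ppm,"42 samples; published measured P75 0.33 ppm; GSD synthetic (2.0), GM back-solved to match"
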