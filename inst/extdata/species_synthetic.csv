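species,functional_group,typical_speed_ms,max_speed_ms,max_dive_depth_m,dive_duration_s,surface_time_s,responds_to_noise,aversion_sd_default,heading_sd,audiogram_file
gray seal,pinniped-in-water,1.5,2.5,300,360,90,TRUE,1.0,1.0,audiogram_gray_seal_synthetic.csv
harbor porpoise,high-frequency cetacean,1.4,4.3,220,110,60,TRUE,0.5,1.0,audiogram_harbor_porpoise_synthetic.csv
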