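group,f_low_khz,f_high_khz,pts_nonpulse_db,tts_nonpulse_db
low-frequency cetacean,0.007,22,215,195
mid-frequency cetacean,0.15,160,215,195
high-frequency cetacean,0.2,180,215,195
pinniped-in-water,0.075,75,203,183
pinniped-in-air,0.075,30,NA,NA
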