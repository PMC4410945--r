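field,B0,C1,C2,R2E0,TE_actual_s,TE_optimal_s,beta,snr_preset
1.5T,1.5,7.2,95.1,11.6,0.050,0.050,1.5,0.45
3T,3.0,13.8,276.0,18.1,0.017,0.035,1.3,1.3
7T,7.0,75.2,831.9,30.8,0.017,0.025,1.0,2.5
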