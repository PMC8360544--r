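parameter,kind,arm,lower,upper
pneumonia_episode,cost,NA,121,5804
bed_day,cost,NA,57,85
pn,prob,no_mouthwash,0.03,0.05
pn_ccu,prob,no_mouthwash,0.43,0.64
pn_mv,prob,no_mouthwash,0.10,0.40
np_ccu,prob,no_mouthwash,0.08,0.11
np_mv,prob,no_mouthwash,0.14,0.30
np_ccu_nomv_died,prob,no_mouthwash,0.01,0.08
pn,prob,mouthwash,0.03,0.05
pn_ccu,prob,mouthwash,0.43,0.64
pn_mv,prob,mouthwash,0.10,0.40
np_ccu,prob,mouthwash,0.08,0.11
np_mv,prob,mouthwash,0.14,0.30
np_ccu_nomv_died,prob,mouthwash,0.01,0.08
pn_ccu_nomv,los,no_mouthwash,15.19,22.79
pn_ccu_mv,los,no_mouthwash,16.90,25.34
pn_ward,los,no_mouthwash,9.09,13.63
pn_ccu_nomv,los,mouthwash,15.19,22.79
pn_ccu_mv,los,mouthwash,16.90,25.34
pn_ward,los,mouthwash,9.09,13.63
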