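name,label,events,total,value,distribution
pn,"Pneumonia",39,931,0.04,beta_counts
pn_ccu,"Critical care unit (pneumonia)",21,39,0.54,beta_counts
pn_mv,"MV (pneumonia, critical care)",NA,NA,0.25,beta_counts
pn_mv_died,"Died after MV (pneumonia)",10,21,0.48,beta_counts
pn_ccu_nomv_died,"Died in critical care, no MV (pneumonia)",17,42,0.40,beta_counts
pn_ward_died,"Died in general ward (pneumonia)",3,75,0.04,beta_counts
np_ccu,"Critical care unit (no pneumonia)",85,887,0.10,beta_counts
np_mv,"MV (no pneumonia, critical care)",NA,NA,0.24,fixed
np_mv_died,"Died after MV (no pneumonia)",NA,NA,0.04,fixed
np_ccu_nomv_died,"Died in critical care, no MV (no pneumonia)",29,85,0.34,beta_counts
np_ward_died,"Died in general ward (no pneumonia)",25,802,0.03,beta_counts
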