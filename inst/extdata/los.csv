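pathway_class,label,mean_days
pn_ccu_mv,"Pneumonia, critical care unit, MV",21.12
pn_ccu_nomv,"Pneumonia, critical care unit, no MV",18.31
pn_ward,"Pneumonia, general ward",11.36
np_ccu_mv,"No pneumonia, critical care unit, MV",15.32
np_ccu_nomv,"No pneumonia, critical care unit, no MV",12.51
np_ward,"No pneumonia, general ward",6.69
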