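name,label,setting,source_currency,source_year,raw_value,adjusted_2020_intl_usd,unit,distribution
pneumonia_episode,"Pneumonia episode",USA,USD,2011,23030,3752,per_episode,gamma
bed_day,"General ward bed day",South Africa,USD,2008,58,71,per_day,gamma
icu_day,"Critical care unit day",UK,GBP,2015,487,1210,per_day,gamma
chlorhexidine,"Chlorhexidine mouthwash (2 doses)",UK,GBP,2020,8,3,per_patient,gamma
mv_episode,"Mechanical ventilation",UK,GBP,2018,242,89,per_episode,gamma
procedure,"Procedure",South Africa,GBP,2015,1670,1423,per_patient,gamma
covid,"COVID-19 cost per patient",South Africa,USD,2019,248,254,per_patient,gamma
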