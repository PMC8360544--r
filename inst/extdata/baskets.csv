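setting,item,unit_cost
UK,"healthcare basket (aggregate of bed-day, critical care, outpatient, drug, laboratory, laparotomy, radiology)",8759
South Africa,"healthcare basket (aggregate of bed-day, critical care, outpatient, drug, laboratory, laparotomy, radiology)",4519
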