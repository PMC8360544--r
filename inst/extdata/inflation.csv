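currency,year,factor
USD,2008,1.06484
USD,2009,1.06484
USD,2010,1.06484
USD,2011,1.06484
USD,2012,1.06484
USD,2013,1.06484
USD,2014,1.06484
USD,2015,1.06484
USD,2016,1.06484
USD,2017,1.06484
USD,2018,1.06484
USD,2019,1.06484
GBP,2015,1.02
GBP,2016,1.02
GBP,2017,1.02
GBP,2018,1.02
GBP,2019,1.02
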