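preset_id,country,year,male_share_total,adol_share_female,adol_share_male,male_share_illustrative,adol_female_illustrative,adol_male_illustrative
ZAMBIA,Zambia,2007,0.453,0.289,0.268,FALSE,FALSE,FALSE
MAI06,Mali,2006,0.208,0.168,0.268,FALSE,TRUE,TRUE
HAI12,Haiti,2012,0.412,0.250,0.268,FALSE,FALSE,TRUE
SEN10,Senegal,2010,0.296,0.050,0.268,TRUE,FALSE,TRUE
LES09,Lesotho,2009,0.296,0.168,0.420,TRUE,TRUE,FALSE
MAI12,Mali,2012,0.296,0.168,0.130,TRUE,TRUE,FALSE
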