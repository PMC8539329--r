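polymer,mw,length_nm,counterion,salt_006,salt_06,salt_6
PAM,3413.81,11.8,0,4,36,361
HPAM,3413.53,11.8,12,4,36,361
PAMPS,5035.69,11.8,12,4,36,361
PAA,3412.69,11.8,48,4,36,361
PEO,1427.72,11.5,0,4,36,361
GUAR,5855.16,12.5,0,4,36,361
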