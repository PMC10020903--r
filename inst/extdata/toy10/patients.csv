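patient_id,sex,race,smoking_status
P01,female,white,current
P02,male,african_american,current
P03,female,white,unknown
P04,male,other,current
P05,female,white,unknown
P06,male,white,current
P07,female,african_american,unknown
P08,male,white,never
P09,female,other,former
P10,male,white,never
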