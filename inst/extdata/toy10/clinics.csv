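clinic_id,name,go_live_date,screening_alert,support_alert
C1,Oncology A,2020-01-06,TRUE,TRUE
C2,Oncology B,2020-02-03,TRUE,FALSE
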