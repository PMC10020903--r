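encounter_id,flowsheet_name,flowsheet_value,recorded_time
E01,Q1,Within the past 7 days,2020-01-10T09:30:00Z
E01,Q2,Yes,2020-01-10T09:31:00Z
E01,Q3,Advice given,2020-01-10T09:32:00Z
E02,Q1,Within the past 7 days,2020-04-15T10:05:00Z
E02,Q2,No,2020-04-15T10:06:00Z
E06,Q3,Advice given,2020-03-02T08:45:00Z
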