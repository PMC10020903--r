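encounter_id,patient_id,clinic_id,encounter_type,start_time
E01,P01,C1,office_visit,2020-01-10T09:00:00Z
E02,P02,C1,office_visit,2020-04-15T10:00:00Z
E03,P03,C1,lab_visit,2020-07-20T11:00:00Z
E04,P04,C1,treatment_visit,2020-11-10T09:30:00Z
E05,P05,C1,office_visit,2020-02-05T14:00:00Z
E06,P06,C1,follow_up,2020-03-02T08:30:00Z
E07,P07,C2,initial_consult,2020-02-10T13:00:00Z
E08,P08,C2,office_visit,2020-05-05T09:00:00Z
E09,P09,C2,follow_up,2020-06-06T10:00:00Z
E10,P10,C2,office_visit,2021-02-20T09:00:00Z
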