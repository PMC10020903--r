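alert_id,alert_instance_id,alert_name,encounter_id,patient_id,firing_time,response_time,triggering_condition,subsequent_action,override_reason,signed_order
A1,A1-01,screening,E01,P01,2020-01-10T09:00:00Z,2020-01-10T09:00:30Z,chart_open,acknowledge_override_warning,Defer,
A1,A1-02,screening,E01,P01,2020-01-10T09:10:30Z,2020-01-10T09:10:52Z,timer_refire,acknowledge_override_warning,Defer,
A1,A1-03,screening,E01,P01,2020-01-10T09:23:00Z,2020-01-10T09:23:53Z,chart_reopen,acknowledge_override_warning,Documented in Flowsheet,
A2,A2-01,screening,E02,P02,2020-04-15T10:00:00Z,2020-04-15T10:00:40Z,chart_open,acknowledge_override_warning,Documented in Flowsheet,
A3,A3-01,screening,E03,P03,2020-07-20T11:00:00Z,2020-07-20T11:00:10Z,chart_open,acknowledge_override_warning,Defer,
A3,A3-02,screening,E03,P03,2020-07-20T11:10:10Z,2020-07-20T11:10:15Z,timer_refire,acknowledge_override_warning,Not appropriate,
A4,A4-01,screening,E04,P04,2020-11-10T09:30:00Z,,noninterruptive_display,none,,
A5,A5-01,screening,E05,P05,2020-02-05T14:00:00Z,2020-02-05T14:00:20Z,chart_open,acknowledge_override_warning,Defer,
A6,A6-01,screening,E06,P06,2020-03-02T08:30:00Z,2020-03-02T08:30:40Z,noninterruptive_display,acknowledge_override_warning,Documented in Flowsheet,
A7,A7-01,screening,E07,P07,2020-02-10T13:00:00Z,2020-02-10T13:00:30Z,chart_open,acknowledge_override_warning,Documented in Flowsheet,
A8,A8-01,support,E01,P01,2020-01-10T09:40:00Z,2020-01-10T09:40:50Z,chart_open,acknowledge_override_warning,Discussed - Ready to quit,REF-TOBACCO
A9,A9-01,support,E02,P02,2020-04-15T10:10:00Z,2020-04-15T10:10:40Z,chart_open,acknowledge_override_warning,Defer,
A9,A9-02,support,E02,P02,2020-04-15T10:20:40Z,2020-04-15T10:21:07Z,timer_refire,acknowledge_override_warning,Defer,
A9,A9-03,support,E02,P02,2020-04-15T10:31:07Z,2020-04-15T10:31:19Z,timer_refire,acknowledge_override_warning,Not discussed,
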