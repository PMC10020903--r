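# Example simulator configuration (two clinics, small volumes).
# Any field of sim_config() can be set here; omitted fields keep their
# defaults, which encode the monitored program's observed behavior rates.
clinics:
  - clinic_id: C1
    name: Oncology A
    go_live_date: '2020-01-06'
    screening_alert: true
    support_alert: true
    n_encounters: 300
  - clinic_id: C2
    name: Oncology B
    go_live_date: '2020-02-03'
    screening_alert: true
    support_alert: false
    n_encounters: 200
p_ack_complete: 0.55
p_document_given_ack: 0.58
seed: 42
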