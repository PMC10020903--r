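# Example calibration: 12 months of monitoring a two-alert tobacco-cessation
# CDS program across seven cancer clinics (three medical oncology M1-M3,
# three radiation oncology R1-R3, one survivorship clinic S; M1 and R1
# implemented the screening alert only).
#
# Aggregate counts (total fired encounters, acknowledgments, documentation,
# support-alert response categories, relevance split, overall and per-clinic
# firing rates, fixed handling durations) reproduce the program's published
# 12-month monitoring summary. The program reported per-clinic firing RATES
# but not the underlying per-clinic fired/completed counts, so the per-clinic
# allocations below are SYNTHETIC: integer counts chosen so that every
# per-clinic rate matches to one decimal place and every aggregate count is
# reproduced exactly. Durations are fixed constants (not distributions) so
# that handling-time means are exact.
durations_s:
  screening_complete: 53
  screening_postpone: 52
  support_complete: 50
  support_postpone: 67
  other: 10
encounter_types:
  relevant: [office_visit, initial_consult, follow_up]
  less_relevant: [lab_visit, treatment_visit]
clinics:
  - clinic_id: M1
    name: Medical oncology 1
    go_live_date: '2019-06-03'
    screening:
      fired: 800
      ack_completed: 300
      ack_interruptive: 240
      documented: 150
      not_appropriate: 250
      defer_only: 0
      no_response: 250
      less_relevant_fired: 120
      less_relevant_ack: 4
      extra_interruptive_firings: 936
  - clinic_id: M2
    name: Medical oncology 2
    go_live_date: '2019-07-01'
    screening:
      fired: 600
      ack_completed: 450
      ack_interruptive: 400
      documented: 380
      not_appropriate: 75
      defer_only: 0
      no_response: 75
      less_relevant_fired: 50
      less_relevant_ack: 3
      extra_interruptive_firings: 120
    support:
      fired: 600
      discussed: 480
      discussed_postponed: 124
      ready_to_quit: 90
      referral: 15
      extra_firings: 264
  - clinic_id: M3
    name: Medical oncology 3
    go_live_date: '2019-08-05'
    screening:
      fired: 2000
      ack_completed: 1300
      ack_interruptive: 1050
      documented: 700
      not_appropriate: 350
      defer_only: 0
      no_response: 350
      less_relevant_fired: 300
      less_relevant_ack: 10
      extra_interruptive_firings: 1260
    support:
      fired: 290
      discussed: 90
      discussed_postponed: 7
      ready_to_quit: 25
      referral: 4
      extra_firings: 7
  - clinic_id: R1
    name: Radiation oncology 1
    go_live_date: '2019-09-02'
    screening:
      fired: 400
      ack_completed: 200
      ack_interruptive: 170
      documented: 120
      not_appropriate: 100
      defer_only: 0
      no_response: 100
      less_relevant_fired: 60
      less_relevant_ack: 2
      extra_interruptive_firings: 187
  - clinic_id: R2
    name: Radiation oncology 2
    go_live_date: '2019-10-07'
    screening:
      fired: 150
      ack_completed: 120
      ack_interruptive: 110
      documented: 100
      not_appropriate: 15
      defer_only: 0
      no_response: 15
      less_relevant_fired: 10
      less_relevant_ack: 1
      extra_interruptive_firings: 0
    support:
      fired: 69
      discussed: 30
      discussed_postponed: 0
      ready_to_quit: 6
      referral: 1
      extra_firings: 0
  - clinic_id: R3
    name: Radiation oncology 3
    go_live_date: '2020-01-06'
    screening:
      fired: 1000
      ack_completed: 400
      ack_interruptive: 375
      documented: 170
      not_appropriate: 300
      defer_only: 0
      no_response: 300
      less_relevant_fired: 130
      less_relevant_ack: 3
      extra_interruptive_firings: 1125
    support:
      fired: 75
      discussed: 25
      discussed_postponed: 0
      ready_to_quit: 5
      referral: 1
      extra_firings: 0
  - clinic_id: S
    name: Cancer survivorship
    go_live_date: '2020-02-03'
    screening:
      fired: 171
      ack_completed: 47
      ack_interruptive: 41
      documented: 27
      not_appropriate: 62
      defer_only: 0
      no_response: 62
      less_relevant_fired: 26
      less_relevant_ack: 1
      extra_interruptive_firings: 480
    support:
      fired: 40
      discussed: 15
      discussed_postponed: 5
      ready_to_quit: 3
      referral: 1
      extra_firings: 5
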