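# Example encounter-type relevance map: which encounter types physicians
# consider appropriate occasions for routine tobacco screening.
# Institutional lists differ; replace with your own classification.
office_visit: relevant
initial_consult: relevant
follow_up: relevant
lab_visit: less_relevant
treatment_visit: less_relevant
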