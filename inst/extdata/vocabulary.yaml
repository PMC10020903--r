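# Default action vocabulary: raw override-reason button label -> canonical
# action. Local deployments replace this file.
"Documented in Flowsheet": ack_complete_screening
"Defer": defer
"Not appropriate": not_appropriate
"Discussed - Ready to quit": discussed_ready
"Discussed - Not ready to quit": discussed_not_ready
"Not discussed": not_discussed
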