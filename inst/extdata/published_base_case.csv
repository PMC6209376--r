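strategy,cost,qaly
no_screening,289013.77,37.73
opportunistic_treatment,363692.85,37.75
systematic_photography,9351964.25,40.47
opportunistic_examination,9520867.26,40.12
systematic_examination,12309783.34,40.68
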