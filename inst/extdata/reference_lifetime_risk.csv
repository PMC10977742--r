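sex,scenario,risk
M,status_quo,33.1
M,scenario1,29.3
M,scenario2,30.0
M,scenario3,26.6
F,status_quo,30.1
F,scenario1,25.5
F,scenario2,25.5
F,scenario3,21.9
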