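"well_id","electrode_id","start","end","n_spikes"
"A1","R1C1",10,10.25,6
"A1","R1C1",20,20.32,5
"A1","R1C2",10.02,10.3,8
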