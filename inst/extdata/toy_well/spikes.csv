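well_id,electrode_id,time_s
A1,R1C1,10.0000000
A1,R1C1,10.0500000
A1,R1C1,10.1000000
A1,R1C1,10.1500000
A1,R1C1,10.2000000
A1,R1C1,10.2500000
A1,R1C1,20.0000000
A1,R1C1,20.0800000
A1,R1C1,20.1600000
A1,R1C1,20.2400000
A1,R1C1,20.3200000
A1,R1C1,50.0000000
A1,R1C1,100.0000000
A1,R1C1,200.0000000
A1,R1C2,10.0200000
A1,R1C2,10.0600000
A1,R1C2,10.1000000
A1,R1C2,10.1400000
A1,R1C2,10.1800000
A1,R1C2,10.2200000
A1,R1C2,10.2600000
A1,R1C2,10.3000000
A1,R1C2,150.0000000
A1,R1C2,150.0500000
A1,R1C2,150.1000000
A1,R1C2,150.1500000
A1,R1C2,250.0000000
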