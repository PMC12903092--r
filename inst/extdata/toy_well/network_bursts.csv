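"well_id","start","end","class","anchor","n_participating"
"A1",9.98,10.34,"main",NA,2
"A1",19.96,20.36,"main",NA,1
"A1",21,21.2,"fragment",2,1
"A1",22,22.1,"fragment",2,1
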