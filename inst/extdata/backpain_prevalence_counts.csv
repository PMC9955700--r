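population,trait,n_case,n_control
twins,lbp_life,158,1144
twins,tlbp_current,124,1171
siblings,lbp_life,51,369
siblings,tlbp_current,42,378
mothers,lbp_life,269,371
mothers,tlbp_current,170,470
fathers,lbp_life,226,340
fathers,tlbp_current,131,435
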