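trait,zygosity,Nc,Nd,N00
lbp_life,MZ,19,41,215
lbp_life,DZ,10,59,307
tlbp_current,MZ,13,36,223
tlbp_current,DZ,5,52,316
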