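name,start,end
alpha1,16,24
alpha2,28,36
beta2_TT,55,60
beta4_TT,77,82
beta6_TT,96,101
beta8_TT,117,122
beta9_TT_beta10,126,133
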