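sex,age_min,age_max,weight
any,0,3,0.27
any,4,6,0.45
any,7,10,0.61
male,11,17,0.86
female,11,17,0.78
male,18,120,1.00
female,18,120,0.76
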