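characteristic,value
n_total,4611
n_male,2055
n_female,2556
age_median,5.91
age_q1,1.88
age_q3,12.47
n_with_height,3235
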