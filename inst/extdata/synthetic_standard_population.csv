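age_lower,age_upper,weight
50,55,0.19
55,60,0.17
60,65,0.15
65,70,0.13
70,75,0.11
75,80,0.09
80,85,0.07
85,90,0.05
90,110,0.04
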