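age,ratio
50,8.0
55,7.0
60,5.5
65,4.5
70,3.8
75,3.2
80,2.8
85,2.5
90,2.3
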