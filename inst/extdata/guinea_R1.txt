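# progressively first-failure censored subsample, k=2 n=36 m=18, R=(18,0*17)
12
24
32
32
34
38
54
55
58
60
61
65
68
70
91
109
110
143
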