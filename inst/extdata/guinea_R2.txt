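# progressively first-failure censored subsample, k=2 n=36 m=18, R=(1*18)
12
15
22
24
32
32
33
34
38
43
44
54
55
58
60
65
68
70
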