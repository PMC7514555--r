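# 36 first-failure group minima (k = 2, n = 36); one published random grouping
12
15
22
24
32
32
33
34
38
38
43
44
48
52
54
55
56
58
58
60
60
61
63
65
65
68
70
70
73
76
84
91
109
110
129
143
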