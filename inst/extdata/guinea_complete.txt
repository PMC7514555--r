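# 72 guinea-pig survival times (days); complete data
12
15
22
24
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
53
54
54
55
56
57
58
58
59
60
60
60
60
61
62
63
65
65
67
68
70
70
72
73
75
76
76
81
83
84
85
87
91
95
96
98
99
109
110
121
127
129
131
143
146
146
175
175
211
233
258
258
263
297
341
341
376
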