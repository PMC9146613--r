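week,count
20,1480
21,1480
22,1850
23,2220
24,2590
25,2960
26,3330
27,3700
28,4440
29,5550
30,7400
31,10360
32,14800
33,20350
34,40700
35,62900
36,131350
37,333000
38,647500
39,1517000
40,592000
41,222000
42,55500
43,11100
44,4440
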