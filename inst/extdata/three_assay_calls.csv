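ID,Myriad_HRD,Amoy_HRD,Myriad_GI,Amoy_GI,OncoScan_GI,Myriad_BRCA,Amoy_BRCA
1,Positive,Positive,Positive,Positive,Positive,No,No
2,Positive,Positive,Positive,Negative,-,Yes,Yes
3,Negative,Negative,Negative,Negative,Negative,No,No
4,Negative,Negative,Negative,Negative,Negative,No,No
5,Positive,Positive,Positive,Positive,Positive,Yes,Yes
6,Positive,Positive,Positive,Positive,Negative,No,No
7,Negative,Negative,Negative,Negative,Positive,No,No
8,Positive,Positive,Positive,Positive,Positive,No,No
9,Positive,Positive,Positive,Positive,Positive,Yes,Yes
10,Negative,Negative,Negative,Negative,Negative,No,No
11,Negative,Negative*,Negative,Negative*,Negative,No,No
12,Positive,Positive,Positive,Positive,Positive,No,No
13,Positive,Positive,Positive,Positive,Negative,No,No
14,Negative,Negative,Negative,Negative,Positive,No,No
15,Positive,Positive,Positive,Positive,Positive,No,No
16,Positive,Positive,Negative,Positive,Positive,Yes,Yes
17,Inconclusive,Negative,Inconclusive,Negative,Negative,No,No
18,Negative,Positive,Negative,Negative,Negative,No,Yes
19,Positive,Positive,Positive,Positive,Positive,No,No
20,Positive,Positive,Positive,Positive,Positive,Yes,No
21,Positive,Positive,Positive,Positive,Positive,No,Yes
22,Negative,Negative,Negative,Negative,Positive,No,No
23,Positive,Positive,Positive,Positive,Positive,No,No
24,Positive,Positive,Positive,Positive,-,Yes,No
25,Positive,Positive,Positive,Positive,-,Yes,No
26,Positive,Positive,Positive,Positive,Positive,No,No
27,Positive,Positive,Positive,Positive,Positive,No,Yes
28,Positive,Positive,Positive,Positive,Positive,No,No
29,Inconclusive,Negative,Inconclusive,Negative,Negative,No,No
30,Negative,Negative*,Negative,Negative*,Negative,No,No
31,Negative,Negative*,Negative,Negative*,Negative,No,No
32,Positive,Positive,Positive,Positive,Positive,No,No
33,Negative,Negative,Negative,Negative,Negative,No,No
34,Negative,Negative,Negative,Negative,Negative,No,No
35,Negative,Positive,Negative,Positive,Negative,No,No
36,Positive,Positive,Positive,Positive,-,Yes,No
37,Negative,Positive,Negative,Positive,Positive,No,No
38,Positive,Positive,Positive,Positive,-,Yes,Yes
39,Positive,Positive,Negative,Negative,-,Yes,Yes
40,Negative,Negative*,Negative,Negative*,Negative,No,No
41,Positive,Positive,Inconclusive,Positive,-,Yes,Yes
42,Positive,Positive,Positive,Positive,Positive,No,No
43,Negative,Positive,Negative,Positive,Positive,No,No
44,Positive,Positive,Inconclusive,Positive,Positive,Yes,No
45,Negative,Negative,Negative,Negative,Negative,No,No
46,Positive,Positive,Negative,Positive,Negative,Yes,No
47,Negative,Negative,Negative,Negative,Negative,No,No
48,Negative,Positive,Negative,Positive,Positive,No,No
49,Negative,Negative,Negative,Negative,Negative,No,No
50,Positive,Positive,Positive,Positive,Positive,No,No
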