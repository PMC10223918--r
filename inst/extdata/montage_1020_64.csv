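index,label
1,Fp1
2,Fpz
3,Fp2
4,AF3
5,AF4
6,F7
7,F5
8,F3
9,F1
10,Fz
11,F2
12,F4
13,F6
14,F8
15,FT7
16,FC5
17,FC3
18,FC1
19,FCz
20,FC2
21,FC4
22,FC6
23,FT8
24,T7
25,C5
26,C3
27,C1
28,Cz
29,C2
30,C4
31,C6
32,T8
33,M1
34,TP7
35,CP5
36,CP3
37,CP1
38,CPz
39,CP2
40,CP4
41,CP6
42,TP8
43,M2
44,P7
45,P5
46,P3
47,P1
48,Pz
49,P2
50,P4
51,P6
52,P8
53,PO7
54,PO5
55,PO3
56,POz
57,PO4
58,PO6
59,PO8
60,CB1
61,O1
62,Oz
63,O2
64,CB2
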