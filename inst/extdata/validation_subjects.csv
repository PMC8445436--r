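subject,sen,spe,ratz
01,0.933,0.988,0.922
02,1,1,1
03,0.933,1,1
04,1,1,1
05,1,0.988,1
06,1,1,1
07,1,1,1
08,1,0.988,1
09,1,1,1
10,1,0.976,1
11,1,1,1
12,1,1,1
13,1,1,1
14,1,0.988,1
15,1,0.988,1
16,1,0.976,1
17,0.933,0.988,0.922
18,1,1,1
19,0.933,0.988,0.922
20,1,0.988,1
21,1,0.988,1
22,0.933,1,1
23,1,1,1
24,1,1,1
25,1,0.988,1
26,1,1,1
27,0.933,1,1
28,1,1,1
29,0.867,0.988,0.916
30,1,1,1
31,1,1,1
32,0.933,0.988,0.922
33,1,1,1
34,1,1,1
35,1,1,1
36,0.867,0.906,0.831
37,1,1,1
38,1,0.988,1
39,1,1,1
40,0.933,0.965,0.920
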