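item,factor
1,anger
2,anger
3,anger
4,anger
5,tension
6,tension
7,tension
8,tension
9,depression
10,depression
11,depression
12,depression
13,vigor
14,vigor
15,vigor
16,vigor
17,fatigue
18,fatigue
19,fatigue
20,fatigue
21,confusion
22,confusion
23,confusion
24,confusion
25,happy
26,happy
27,happy
28,happy
29,calmness
30,calmness
31,calmness
32,calmness
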