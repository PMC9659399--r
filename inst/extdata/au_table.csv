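core_index,facs_name,au_number
1,inner brow raiser,1
2,outer brow raiser,2
3,brow lowerer,4
4,upper lid raiser,5
5,cheek raiser,6
6,lid tightener,7
7,nose wrinkler,9
8,upper lip raiser,10
9,nasolabial deepener,11
10,lip corner puller,12
11,sharp lip puller,13
12,dimpler,14
13,lip corner depressor,15
14,lower lip depressor,16
15,chin raiser,17
16,lip pucker,18
17,lip stretcher,20
18,lip funneler,22
19,lip tightener,23
20,lip pressor,24
21,lips part,25
22,jaw drop,26
23,mouth stretch,27
24,inner brow raiser (left),1
25,inner brow raiser (right),1
26,outer brow raiser (left),2
27,outer brow raiser (right),2
28,brow lowerer (left),4
29,brow lowerer (right),4
30,upper lid raiser (left),5
31,upper lid raiser (right),5
32,cheek raiser (left),6
33,cheek raiser (right),6
34,lid tightener (left),7
35,lid tightener (right),7
36,lip corner puller (left),12
37,lip corner puller (right),12
38,dimpler (left),14
39,dimpler (right),14
40,lip corner depressor (left),15
41,lip corner depressor (right),15
42,lip stretcher (left),20
43,lip stretcher (right),20
44,nose wrinkler (left),9
45,nose wrinkler (right),9
46,lip suck,28
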