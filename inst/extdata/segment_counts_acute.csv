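patient,ct_segments,lge_segments,edema_segments,concordance
1,13,12,4,partial
2,8,6,4,partial
3,19,6,10,partial
4,13,10,6,partial
5,1,1,1,total
6,7,5,4,partial
7,13,13,0,total
9,12,12,2,total
10,10,10,5,total
11,16,2,2,partial
12,7,7,2,total
13,2,2,1,total
14,9,9,4,total
15,6,6,3,total
16,3,3,0,total
17,6,6,3,total
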