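patient,ct_segments,lge_segments,edema_segments,concordance
1,7,6,2,partial
3,8,6,1,partial
8,10,10,0,total
11,5,5,0,total
12,7,7,0,total
13,2,2,0,total
14,10,10,0,total
15,2,2,0,total
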