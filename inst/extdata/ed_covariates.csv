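cluster,patient_volume,mh_team,urgent_followup
1,1,1,1
2,0,0,0
3,1,1,0
4,1,1,0
5,0,1,1
6,1,0,1
7,0,0,1
8,0,0,0
9,0,0,0
10,0,1,0
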