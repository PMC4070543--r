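"",7,8,9,10,11,12
7,17,1,2,0,0,0
8,3,15,1,1,0,0
9,5,1,11,2,0,1
10,6,5,1,6,1,1
11,4,4,1,1,9,1
12,7,3,1,2,1,6
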