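cycle_length,n,mean_follicular,f_lo,f_hi,mean_luteal,l_lo,l_hi
23,120,10.5,7,15,11.5,7,15
24,324,11.1,7,15,11.9,8,16
25,657,11.5,8,16,12.5,8,16
26,1065,12.1,9,16,12.9,9,16
27,1407,12.7,10,16,13.3,10,16
28,1637,13.4,10,17,13.6,10,17
29,1516,14.1,11,17,13.9,11,17
30,1392,15,11,19,14,10,18
31,1144,15.7,12,20,14.3,10,18
32,875,16.4,12,20,14.6,11,19
33,707,17.4,13,21,14.6,11,19
34,557,18.1,12,23,14.9,10,21
35,395,18.8,11,26,15.2,8,23
36,300,19.6,12,25,15.4,10,23
37,204,20.1,12,25,15.9,11,24
38,162,21.5,14,28,15.5,9,23
39,145,21.6,12,29,16.4,9,26
40,124,22.3,12,29,16.7,10,27
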