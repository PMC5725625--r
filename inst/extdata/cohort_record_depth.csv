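mean_cycle_length,k1,k2,k3,k4,k5,k6,k7,k8
24,176,168,117,121,90,91,67,68
25,438,496,384,385,325,313,282,272
26,878,918,805,798,694,700,625,608
27,1253,1291,1194,1222,1129,1083,1003,911
28,1569,1529,1507,1440,1382,1293,1196,1154
29,1620,1541,1472,1361,1306,1270,1178,1078
30,1396,1328,1292,1238,1181,1074,998,934
31,1101,1024,1036,979,964,895,860,785
32,862,856,867,728,715,647,624,560
33,721,637,564,569,520,463,429,378
34,532,448,461,371,362,301,276,225
35,377,353,314,253,226,188,195,174
36,290,214,194,179,141,110,88,76
37,219,160,125,90,74,65,47,42
total,11640,11093,10421,9804,9154,8529,7898,7285
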