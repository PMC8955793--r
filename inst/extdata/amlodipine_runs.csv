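run,U,MD,pH,Rs,Rs_sd,t2,t2_sd
1,20,10,2.0,1.73,0.03,12.15,0.47
2,15,8.75,2.0,1.80,0.02,16.42,0.39
3,15,10,4.0,1.61,0.05,11.37,0.55
4,15,10,2.0,2.10,0.06,17.83,0.64
5,15,10,3.0,1.96,0.08,16.06,0.58
6,17.5,10,2.0,1.93,0.02,14.73,0.32
7,17.5,7.5,3.0,1.40,0.03,10.46,0.37
8,15,7.5,2.0,1.59,0.04,15.58,0.80
9,20,7.5,2.0,1.31,0.02,10.28,0.36
10,20,10,4.0,1.47,0.03,7.80,0.42
11,20,8.75,3.0,1.50,0.02,10.19,0.02
12,17.5,8.75,4.0,1.49,0.08,8.88,0.77
13,20,8.75,2.0,1.46,0.01,10.27,0.17
14,15,7.5,4.0,1.19,0.04,8.62,0.37
15,20,7.5,4.0,1.07,0.04,6.04,0.31
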