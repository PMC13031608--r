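run_id,round_id,ZmPAL,At4CL4,GmCHS,MsCHR,ZmCHI,CoA,ATP,NADPH,tyrosine,pH,temperature,time,volume,response,replicate_sd,n_reps
1,0,-1,1,-1,1,-1,1,1,1,1,-1,-1,1,1,50.43,0.05,3
2,0,1,1,-1,1,1,-1,-1,-1,-1,1,-1,1,-1,52.41,1.96,3
3,0,1,1,-1,-1,1,1,-1,1,1,-1,-1,-1,-1,14.24,1.81,3
4,0,-1,-1,-1,1,-1,1,-1,1,1,1,1,-1,-1,76.42,2.82,3
5,0,-1,-1,-1,-1,1,-1,1,-1,1,1,1,1,-1,37.36,5.58,3
6,0,1,1,1,-1,-1,1,1,-1,1,1,-1,-1,-1,65.37,3.20,3
7,0,-1,1,1,-1,1,1,-1,-1,-1,-1,1,-1,1,17.45,2.40,3
8,0,-1,-1,1,1,-1,1,1,-1,-1,-1,-1,1,-1,13.96,0.71,3
9,0,-1,-1,1,-1,1,-1,1,1,1,1,-1,-1,1,20.86,4.09,3
10,0,-1,1,1,-1,-1,-1,-1,1,-1,1,-1,1,1,11.41,0.92,3
11,0,1,1,1,1,-1,-1,1,1,-1,1,1,-1,-1,26.45,1.04,3
12,0,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,-1,15.60,2.24,3
13,0,1,-1,1,1,-1,-1,-1,-1,1,-1,1,-1,1,78.59,8.76,3
14,0,1,-1,1,1,1,1,-1,-1,1,1,-1,1,1,66.55,2.24,3
15,0,1,1,-1,-1,-1,-1,1,-1,1,-1,1,1,1,71.43,2.81,3
16,0,-1,1,1,1,1,-1,-1,1,1,-1,1,1,-1,15.94,2.37,3
17,0,1,-1,1,-1,1,1,1,1,-1,-1,1,1,-1,17.81,0.46,3
18,0,-1,1,-1,1,1,1,1,-1,-1,1,1,-1,1,79.64,1.95,3
19,0,1,-1,-1,1,1,-1,1,1,-1,-1,-1,-1,1,58.01,4.77,3
20,0,1,-1,-1,-1,-1,1,-1,1,-1,1,1,1,1,75.77,5.78,3
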