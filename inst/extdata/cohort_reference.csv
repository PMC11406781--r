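participant,side,trials,gaitSpeed,stepLength,support
1,L,5,0.86,0.46,
1,R,5,0.85,0.48,
2,L,4,0.85,0.43,
2,R,4,0.81,0.49,
3,L,2,0.86,0.40,
3,R,2,0.74,0.38,
4,L,5,0.91,0.42,
4,R,5,0.87,0.44,
5,L,5,0.88,0.49,
5,R,5,0.81,0.49,
6,L,4,0.72,0.25,
6,R,4,0.70,0.48,
7,L,3,0.13,0.12,cane and held hand
7,R,3,0.12,0.13,cane and held hand
8,L,5,0.83,0.41,
8,R,5,0.89,0.41,
9,L,4,0.48,0.31,
9,R,4,0.52,0.30,
10,L,3,0.91,0.44,
10,R,3,0.90,0.41,
11,L,3,0.64,0.32,
11,R,3,0.61,0.39,
12,L,3,0.87,0.45,
12,R,3,0.90,0.42,
13,L,5,0.65,0.36,
13,R,5,0.58,0.34,
14,L,2,0.27,0.30,held hand
14,R,2,0.30,0.29,held hand
15,L,6,0.73,0.37,
15,R,6,0.81,0.36,
16,L,4,0.60,0.36,
16,R,4,0.62,0.35,
17,L,2,0.52,0.31,held hand
17,R,2,0.27,0.24,held hand
18,L,4,0.82,0.39,
18,R,4,0.86,0.38,
19,L,3,NA,NA,crutches (2 trials) and walker (1)
19,R,3,NA,NA,crutches (2 trials) and walker (1)
20,L,4,0.73,0.38,
20,R,4,0.74,0.40,
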