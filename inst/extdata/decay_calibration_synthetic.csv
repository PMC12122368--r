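months,survival_percent
0,100
1,96.5
2,92.0
3,89.3
6,79.0
9,72.4
12,63.5
18,52.9
24,43.8
36,33.5
48,27.1
60,24.2
84,21.0
120,20.3
144,20.1
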