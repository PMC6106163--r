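rank,RGIV,host_count
1,81.82,17
2,9.66,8
3,4.55,3
4,2.20,3
5,1.19,6
6,0.41,4
7,0.10,4
8,0.04,3
9,0.02,4
10,0.01,1
11,0.01,2
12,0.00,3
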