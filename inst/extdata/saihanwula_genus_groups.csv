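rank,RGIV,host_count
1,80.29,13
2,11.61,7
3,4.51,7
4,1.82,1
5,1.01,3
6,0.56,5
7,0.13,3
8,0.03,3
9,0.02,2
10,0.01,1
11,0.00,2
12,0.00,3
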