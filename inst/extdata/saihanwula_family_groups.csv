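rank,RGIV,host_count
1,87.13,10
2,10.06,5
3,1.86,3
4,0.69,2
5,0.23,5
6,0.02,1
7,0.00,1
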