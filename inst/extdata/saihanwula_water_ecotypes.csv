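water_ecotype,RGIV,n_species,host_count
hydrophyte,0.00,2,0
hygrophyte,0.72,35,4
hygromesophyte,5.33,37,2
mesophyte,74.01,369,47
mesoxerophyte,10.86,81,8
xeromesophyte,6.85,52,8
xerophyte,2.23,75,2
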