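life_form,RGIV,n_species,host_count
perennial,48.34,458,32
tree,28.48,25,15
shrub,13.57,51,9
annual_biennial,7.73,105,13
subshrub,1.88,12,0
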