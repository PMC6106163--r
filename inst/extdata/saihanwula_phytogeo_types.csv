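phytogeo_type,RGIV,n_species,host_count
east_palaearctic,32.59,90,13
east_asia,23.03,184,26
palaearctic,12.27,94,10
holarctic,8.84,95,9
northeast_china,7.93,14,2
north_china,6.64,20,5
dahuric_mongolia,5.32,74,5
eastern_siberia,1.03,11,0
cosmopolitan,0.68,12,0
unknown,0.66,11,0
mongolia,0.39,2,0
europe_siberia,0.30,5,0
black_sea_kazakhstan_mongolia,0.17,3,0
kazakhstan_mongolia,0.12,11,0
central_asia,0.04,16,0
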