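clade_name,age
vascular_plants,420
angiosperms,140
gymnosperms,310
eudicots,125
core_eudicots,115
Ranunculales,110
fabids,105
Fagales,95
Rosales_Fabales,100
Rosaceae,90
Fabaceae,80
Betulaceae,70
Asterales,85
Asteraceae,50
Malpighiales,90
Salicaceae,60
monocots,120
Poales,100
Poaceae,70
Cyperaceae,65
Pinaceae,160
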