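(((((((Quercus)Fagaceae,(Betula,Corylus)Betulaceae)Fagales,((Prunus,Crataegus,Spiraea)Rosaceae,(Astragalus,Oxytropis,Lespedeza)Fabaceae)Rosales_Fabales)fabids,(((Artemisia,Saussurea,Taraxacum)Asteraceae)Asterales,((Populus,Salix)Salicaceae)Malpighiales)core2)core_eudicots,((Thalictrum,Pulsatilla)Ranunculaceae)Ranunculales)eudicots,(((Stipa,Cleistogenes,Leymus)Poaceae,(Carex,Kobresia)Cyperaceae)Poales)monocots)angiosperms,((Larix,Picea,Pinus)Pinaceae)gymnosperms)vascular_plants;
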