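bin,stage,midpoint_ma
early Permian,Asselian,285.6
early Permian,Sakmarian,285.6
early Permian,Artinskian,285.6
early Permian,Kungurian,285.6
middle Permian,Roadian,265.7
middle Permian,Wordian,265.7
middle Permian,Capitanian,265.7
late Permian,Wuchiapingian,255.5
late Permian,Changhsingian,255.5
Early Triassic,Induan,249.6
Early Triassic,Olenekian,249.6
Anisian,Anisian,244.6
Ladinian,Ladinian,239.5
Carnian,Carnian,232.0
Norian,Norian,217.8
Rhaetian,Rhaetian,204.9
Hettangian,Hettangian,200.3
Sinemurian,Sinemurian,195.0
Pliensbachian,Pliensbachian,186.8
Toarcian,Toarcian,178.4
Middle Jurassic,Aalenian,168.8
Middle Jurassic,Bajocian,168.8
Middle Jurassic,Bathonian,168.8
Middle Jurassic,Callovian,168.8
Oxfordian,Oxfordian,160.4
Kimmeridgian,Kimmeridgian,154.7
Tithonian,Tithonian,148.6
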