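species,stocking,herbivore,season,contribution_pct
Hyparrhenia hirta,low,cattle,wet,56.07
Paspalum dilatatum,low,cattle,wet,9.82
Setaria nigrirostris,low,cattle,wet,0
Themeda triandra,low,cattle,wet,5.2
Paspalum scrobiculatum,low,cattle,wet,10.4
Tristachya leucothrix,low,cattle,wet,0
Chloris gayana,low,cattle,wet,0
Cyprus sedge,low,cattle,wet,0
Eragrostis plana,low,cattle,wet,0
Unknown succulent forb,low,cattle,wet,0
Pennisetum clandestinum,low,cattle,wet,0
Aristida junciformis,low,cattle,wet,8.09
Unknown flat leaf forb,low,cattle,wet,0
Digitaria eriantha,low,cattle,wet,0
Setaria sphacelata var torta,low,cattle,wet,0
Sporobolus africanus,low,cattle,wet,5.78
Eragrostis curvula,low,cattle,wet,0
Heteropogon contortus,low,cattle,wet,0
Cymbopogon excavatus,low,cattle,wet,0
Hyparrhenia hirta,low,oribi,wet,63.92
Paspalum dilatatum,low,oribi,wet,10.82
Setaria nigrirostris,low,oribi,wet,10.57
Themeda triandra,low,oribi,wet,6.44
Paspalum scrobiculatum,low,oribi,wet,2.06
Tristachya leucothrix,low,oribi,wet,1.8
Chloris gayana,low,oribi,wet,1.55
Cyprus sedge,low,oribi,wet,0.77
Eragrostis plana,low,oribi,wet,0.77
Unknown succulent forb,low,oribi,wet,0.77
Pennisetum clandestinum,low,oribi,wet,0.52
Aristida junciformis,low,oribi,wet,0
Unknown flat leaf forb,low,oribi,wet,0
Digitaria eriantha,low,oribi,wet,0
Setaria sphacelata var torta,low,oribi,wet,0
Sporobolus africanus,low,oribi,wet,0
Eragrostis curvula,low,oribi,wet,0
Heteropogon contortus,low,oribi,wet,0
Cymbopogon excavatus,low,oribi,wet,0
Hyparrhenia hirta,low,oribi,dry,88.69
Paspalum dilatatum,low,oribi,dry,3.62
Setaria nigrirostris,low,oribi,dry,0
Themeda triandra,low,oribi,dry,2.71
Paspalum scrobiculatum,low,oribi,dry,0
Tristachya leucothrix,low,oribi,dry,0
Chloris gayana,low,oribi,dry,0.9
Cyprus sedge,low,oribi,dry,0
Eragrostis plana,low,oribi,dry,0
Unknown succulent forb,low,oribi,dry,0
Pennisetum clandestinum,low,oribi,dry,4.07
Aristida junciformis,low,oribi,dry,0
Unknown flat leaf forb,low,oribi,dry,0
Digitaria eriantha,low,oribi,dry,0
Setaria sphacelata var torta,low,oribi,dry,0
Sporobolus africanus,low,oribi,dry,0
Eragrostis curvula,low,oribi,dry,0
Heteropogon contortus,low,oribi,dry,0
Cymbopogon excavatus,low,oribi,dry,0
Hyparrhenia hirta,intermediate,cattle,wet,36.86
Paspalum dilatatum,intermediate,cattle,wet,0
Setaria nigrirostris,intermediate,cattle,wet,0
Themeda triandra,intermediate,cattle,wet,10.2
Paspalum scrobiculatum,intermediate,cattle,wet,6.27
Tristachya leucothrix,intermediate,cattle,wet,7.06
Chloris gayana,intermediate,cattle,wet,0
Cyprus sedge,intermediate,cattle,wet,0
Eragrostis plana,intermediate,cattle,wet,0
Unknown succulent forb,intermediate,cattle,wet,0
Pennisetum clandestinum,intermediate,cattle,wet,14.9
Aristida junciformis,intermediate,cattle,wet,5.49
Unknown flat leaf forb,intermediate,cattle,wet,0
Digitaria eriantha,intermediate,cattle,wet,0
Setaria sphacelata var torta,intermediate,cattle,wet,0
Sporobolus africanus,intermediate,cattle,wet,0
Eragrostis curvula,intermediate,cattle,wet,0
Heteropogon contortus,intermediate,cattle,wet,0
Cymbopogon excavatus,intermediate,cattle,wet,0
Hyparrhenia hirta,intermediate,oribi,wet,79.95
Paspalum dilatatum,intermediate,oribi,wet,0.55
Setaria nigrirostris,intermediate,oribi,wet,4.95
Themeda triandra,intermediate,oribi,wet,12.09
Paspalum scrobiculatum,intermediate,oribi,wet,0
Tristachya leucothrix,intermediate,oribi,wet,0
Chloris gayana,intermediate,oribi,wet,0
Cyprus sedge,intermediate,oribi,wet,0
Eragrostis plana,intermediate,oribi,wet,0
Unknown succulent forb,intermediate,oribi,wet,0
Pennisetum clandestinum,intermediate,oribi,wet,0
Aristida junciformis,intermediate,oribi,wet,0
Unknown flat leaf forb,intermediate,oribi,wet,2.47
Digitaria eriantha,intermediate,oribi,wet,0
Setaria sphacelata var torta,intermediate,oribi,wet,0
Sporobolus africanus,intermediate,oribi,wet,0
Eragrostis curvula,intermediate,oribi,wet,0
Heteropogon contortus,intermediate,oribi,wet,0
Cymbopogon excavatus,intermediate,oribi,wet,0
Hyparrhenia hirta,intermediate,oribi,dry,72.43
Paspalum dilatatum,intermediate,oribi,dry,8.5
Setaria nigrirostris,intermediate,oribi,dry,0
Themeda triandra,intermediate,oribi,dry,6.45
Paspalum scrobiculatum,intermediate,oribi,dry,0
Tristachya leucothrix,intermediate,oribi,dry,0
Chloris gayana,intermediate,oribi,dry,1.47
Cyprus sedge,intermediate,oribi,dry,0
Eragrostis plana,intermediate,oribi,dry,0
Unknown succulent forb,intermediate,oribi,dry,0
Pennisetum clandestinum,intermediate,oribi,dry,6.74
Aristida junciformis,intermediate,oribi,dry,0
Unknown flat leaf forb,intermediate,oribi,dry,0
Digitaria eriantha,intermediate,oribi,dry,0
Setaria sphacelata var torta,intermediate,oribi,dry,0
Sporobolus africanus,intermediate,oribi,dry,0
Eragrostis curvula,intermediate,oribi,dry,1.17
Heteropogon contortus,intermediate,oribi,dry,3.23
Cymbopogon excavatus,intermediate,oribi,dry,0
Hyparrhenia hirta,high,cattle,wet,11.21
Paspalum dilatatum,high,cattle,wet,0
Setaria nigrirostris,high,cattle,wet,6.36
Themeda triandra,high,cattle,wet,25.15
Paspalum scrobiculatum,high,cattle,wet,0
Tristachya leucothrix,high,cattle,wet,0
Chloris gayana,high,cattle,wet,0
Cyprus sedge,high,cattle,wet,0
Eragrostis plana,high,cattle,wet,0
Unknown succulent forb,high,cattle,wet,0
Pennisetum clandestinum,high,cattle,wet,0
Aristida junciformis,high,cattle,wet,0
Unknown flat leaf forb,high,cattle,wet,0
Digitaria eriantha,high,cattle,wet,0
Setaria sphacelata var torta,high,cattle,wet,42.12
Sporobolus africanus,high,cattle,wet,7.88
Eragrostis curvula,high,cattle,wet,0
Heteropogon contortus,high,cattle,wet,0
Cymbopogon excavatus,high,cattle,wet,0
Hyparrhenia hirta,high,oribi,wet,35.29
Paspalum dilatatum,high,oribi,wet,0
Setaria nigrirostris,high,oribi,wet,36.65
Themeda triandra,high,oribi,wet,21.72
Paspalum scrobiculatum,high,oribi,wet,0
Tristachya leucothrix,high,oribi,wet,0.9
Chloris gayana,high,oribi,wet,0
Cyprus sedge,high,oribi,wet,0
Eragrostis plana,high,oribi,wet,0
Unknown succulent forb,high,oribi,wet,0
Pennisetum clandestinum,high,oribi,wet,0
Aristida junciformis,high,oribi,wet,0
Unknown flat leaf forb,high,oribi,wet,0
Digitaria eriantha,high,oribi,wet,2.71
Setaria sphacelata var torta,high,oribi,wet,1.36
Sporobolus africanus,high,oribi,wet,1.36
Eragrostis curvula,high,oribi,wet,0
Heteropogon contortus,high,oribi,wet,0
Cymbopogon excavatus,high,oribi,wet,0
Hyparrhenia hirta,high,oribi,dry,57.68
Paspalum dilatatum,high,oribi,dry,0
Setaria nigrirostris,high,oribi,dry,0
Themeda triandra,high,oribi,dry,24.72
Paspalum scrobiculatum,high,oribi,dry,0
Tristachya leucothrix,high,oribi,dry,0
Chloris gayana,high,oribi,dry,0
Cyprus sedge,high,oribi,dry,0
Eragrostis plana,high,oribi,dry,0
Unknown succulent forb,high,oribi,dry,0
Pennisetum clandestinum,high,oribi,dry,0
Aristida junciformis,high,oribi,dry,0
Unknown flat leaf forb,high,oribi,dry,0
Digitaria eriantha,high,oribi,dry,0
Setaria sphacelata var torta,high,oribi,dry,0
Sporobolus africanus,high,oribi,dry,2.25
Eragrostis curvula,high,oribi,dry,0.74
Heteropogon contortus,high,oribi,dry,14.23
Cymbopogon excavatus,high,oribi,dry,0.37
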