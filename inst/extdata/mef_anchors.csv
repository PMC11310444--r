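condition,reaction,net_flux,description
P,ME1,31.6,cytosolic malic enzyme Mal.c -> Pyr.c
P,MDH1,24.4,cytosolic malate dehydrogenase net OAC.c -> Mal.c
P,PCK1,7.4,PEP carboxykinase OAC.c -> PEP.c
Q,ME1,0,cytosolic malic enzyme Mal.c -> Pyr.c (silenced)
Q,MDH1,-86.6,cytosolic malate dehydrogenase net reversed Mal.c -> OAC.c
Q,PCK1,104,PEP carboxykinase OAC.c -> PEP.c
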