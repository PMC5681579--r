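species,trichoid,basiconic,clavate,coeloconic
Dmel,90,74,26,22
Ccap,285,235,119,141
Ccat,365,285,162,201
Ncya,446,197,212,159
Bzon,642,271,204,174
Zcuc,439,335,151,205
Ddem,654,656,312,391
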