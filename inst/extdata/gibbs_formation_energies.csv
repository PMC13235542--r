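species,phase,dG0f_kJ_mol,N,H,O,charge,source
NH4+,aq,-79.31,1,4,0,1,CODATA 1989
NH3,aq,-26.50,1,3,0,0,Stumm & Morgan (1996)
NO2-,aq,-32.20,1,0,2,-1,Stumm & Morgan (1996)
NO3-,aq,-108.74,1,0,3,-1,CODATA 1989
O2,g,0,0,0,2,0,definition
H2O,l,-237.13,0,2,1,0,CODATA 1989
H+,aq,0,0,1,0,1,definition
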