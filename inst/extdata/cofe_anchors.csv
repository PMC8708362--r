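x,K_J_per_m3,Ms_A_per_m,rho_kg_per_m3
0,11000,480000,5240
0.05,38000,477000,5243
0.1,82000,474000,5245
0.2,156000,469000,5250
0.4,245000,458000,5260
0.67,294000,443000,5270
0.8,290000,436000,5280
1,200000,425000,5290
1.1,180000,NA,NA
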