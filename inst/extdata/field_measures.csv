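group,organic_fertilizer,straw_returning,plowing,energy
G0,0,0,0,-73.608
G1,1,0,0,-85.565
G2,0,1,0,-78.515
G3,0,0,1,-93.523
G4,1,1,0,-95.529
G5,1,0,1,-87.956
G6,0,1,1,-85.619
G7,1,1,1,-104.013
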