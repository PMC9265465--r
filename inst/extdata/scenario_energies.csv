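scenario,group,energy
1,G0,-102.160
1,G5,-113.825
2,G0,-81.934
2,G1,-107.514
2,G3,-99.357
2,G5,-107.943
2,G8,-105.530
3,G0,-110.642
4,G0,-100.372
4,G2,-110.140
4,G3,-106.506
4,G6,-116.439
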