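name,site,group,cv,g1gkq,g1ob0,g5m0k,ploec,logkow,logt12,is_parent
MOX,,,3.696,1.920,1.845,1.922,8.869,0.950,1.975,1
Derivative-1,1,NO,3.823,2.049,1.873,2.062,7.978,0.211,0.965,0
Derivative-2,1,COOH,3.712,2.048,1.880,2.066,8.163,0.541,0.921,0
Derivative-3,2,CH3,4.079,2.051,1.891,2.058,8.389,1.147,1.070,0
Derivative-4,2,C2H5,4.315,2.049,1.889,2.073,8.343,1.258,1.094,0
Derivative-5,2,C3H7,4.592,2.049,1.887,2.093,8.437,1.497,1.117,0
Derivative-6,2,C4H9,4.592,2.049,1.885,2.100,8.537,1.547,1.153,0
Derivative-7,2,C5H11,4.623,2.049,1.883,2.106,8.467,1.643,1.156,0
Derivative-8,2,C=C,4.144,2.050,1.885,2.070,8.373,1.102,1.068,0
Derivative-9,2,CH2NH2,4.088,2.050,1.890,2.064,8.549,0.912,-0.582,0
Derivative-10,2,NH2,4.454,2.047,1.896,2.048,8.808,0.453,-0.219,0
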