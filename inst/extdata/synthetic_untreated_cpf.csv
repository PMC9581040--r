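time_h,phase,division_round,cpf_percent
      0,G1,0,  25.05
      0,S,0,  51.95
      0,G2,0,  17.05
      0,M,0,   5.95
     32,G1,0,   1.55
     32,S,0,   3.65
     32,G2,0,   4.05
     32,M,0,   2.35
     32,G1,1, 45.575
     32,S,1, 30.825
     32,G2,1,  8.425
     32,M,1,  1.625
     32,G1,2,   1.95
     48,G1,0,   1.15
     48,S,0,    1.4
     48,G2,0,   2.15
     48,M,0,   0.75
     48,G1,1,  13.95
     48,S,1, 29.675
     48,G2,1,  13.55
     48,M,1,  5.175
     48,G1,2,   30.4
     48,S,2, 1.7875
     48,G2,2, 0.0125
     72,G1,0,   0.45
     72,S,0,    1.1
     72,G2,0,    1.1
     72,M,0,   0.45
     72,G1,1,  3.925
     72,S,1,  9.775
     72,G2,1,   3.35
     72,M,1,   1.95
     72,G1,2, 30.775
     72,S,2,26.1875
     72,G2,2, 9.1875
     72,M,2, 2.9375
     72,G1,3,8.71875
     72,S,3,0.09375
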