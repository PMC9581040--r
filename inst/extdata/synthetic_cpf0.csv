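time_h,phase,division_round,cpf_percent
      0,G1,0,25.0352
      0,S,0,51.9718
      0,G2,0,17.0423
      0,M,0, 5.9507
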