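enclosing radius: 25.06692 
0.8R time: 49.5 s
rips_persistence: 625 points, Z2, threshold 20.05
  H0: 625 generators, top lifetimes 16.1, 1.98, 1.96
  H1: 590 generators, top lifetimes 13.1, 12.4, 0.765
  H2: 249 generators, top lifetimes 13.4, 1.09, 0.661
betti: 1 2 1 
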