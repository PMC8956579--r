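"time","x","y"
0,0.774191689429334,0.560973930844697
2,1.14667972261693,1.09888619375115
4,1.52444657488021,0.356378232918112
6,1.70403230968448,0.519796282677338
8,1.80037705009323,0.479056197885796
10,1.87143373549796,0.557608771977952
12,2.40405514915203,0.295944897816972
14,2.32802227081825,0
16,3.02510776673246,0
18,2.89656168483531,0.410013083553473
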