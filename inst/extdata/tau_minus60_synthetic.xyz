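8
frame 1 rc=-1.000000
O3p       -0.72469333    -0.23572075    -2.69430052
H3p       -1.19056761    -0.38725552    -4.42635086
Ccarb      0.00000000     0.00000000     0.00000000
Ocarb      1.23000000     0.00000000     0.00000000
Ca        -0.78285787     1.30289430     0.00000000
Ob        -0.78006395    -1.11404678     0.00000000
N         -1.63382660     1.37812852    -1.19628259
P5p       -4.63542786     3.90997143    -3.39404540
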