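20
0000000000
C       -0.262258      -1.361090       0.707303
C       -1.195843      -0.334461       1.307525
C       -1.221354       0.950148       0.913560
C       -0.383552       1.573742      -0.129616
C        1.181546      -0.980796       0.945260
C        1.729754       0.147837       0.463871
C        1.059576       1.181402      -0.349519
C       -0.535967      -1.540556      -0.768736
C       -0.402235      -0.547005      -1.663752
C        0.017007       0.841615      -1.389953
H       -0.447173      -2.320778       1.206013
H       -1.866033      -0.669183       2.088404
H       -1.928298       1.615437       1.404683
H       -0.603259       2.626106      -0.253141
H        1.784092      -1.661535       1.532200
H        2.777662       0.336039       0.687591
H        1.727617       1.992416      -0.608319
H       -0.852892      -2.520961      -1.099385
H       -0.622096      -0.771985      -2.705206
H        0.043707       1.443609      -2.288781
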