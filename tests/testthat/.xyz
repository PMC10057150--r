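24
boronfit frame 1
B       0.00000000     0.00000000     0.00000000
C       1.63000000     0.00000000     0.00000000
C       2.35042487     0.00000000     1.20041160
C       3.75022424    -0.00000000     1.17671116
C       4.42959875    -0.00000000    -0.04740088
C       3.70917388    -0.00000000    -1.24781248
C       2.30937451    -0.00000000    -1.22411204
H       1.82633597     0.00000000     2.14472660
H       4.30598057    -0.00000000     2.10274297
H       5.50944398    -0.00000000    -0.06568407
H       4.23326278    -0.00000000    -2.19212748
H       1.75361818    -0.00000000    -2.15014384
O      -0.50404836     0.71169433     1.23269073
O      -0.50404836     0.71169433    -1.23269073
OG     -0.50404836    -1.42338865     0.00000000
HO     -1.47804836     0.71169433     1.23269073
HO     -1.47804836     0.71169433    -1.23269073
CB     -1.83848997    -1.45014528     0.45458735
HB     -2.45997386    -0.84517254    -0.20561395
HB     -1.88621168    -1.04835238     1.46670647
CA     -2.50878054    -2.75392365    -0.00049233
HA     -1.96750488    -3.60489978     0.41298110
HA     -3.54037016    -2.77460785     0.35092626
HA     -2.49511455    -2.80938854    -1.08899446
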