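@<TRIPOS>MOLECULE
24 24 1 0 0
SMALL
USER_CHARGES
@<TRIPOS>ATOM
      1 B            0.0000     0.0000     0.0000 b      1 LIG   0.680000
      2 C1           1.6300     0.0000     0.0000 ca     1 LIG  -0.100000
      3 C2           2.3504     0.0000     1.2004 ca     1 LIG  -0.100000
      4 C3           3.7502    -0.0000     1.1767 ca     1 LIG  -0.100000
      5 C4           4.4296    -0.0000    -0.0474 ca     1 LIG  -0.100000
      6 C5           3.7092    -0.0000    -1.2478 ca     1 LIG  -0.100000
      7 C6           2.3094    -0.0000    -1.2241 ca     1 LIG  -0.100000
      8 H2           1.8263     0.0000     2.1447 ha     1 LIG   0.130000
      9 H3           4.3060    -0.0000     2.1027 ha     1 LIG   0.130000
     10 H4           5.5094    -0.0000    -0.0657 ha     1 LIG   0.130000
     11 H5           4.2333    -0.0000    -2.1921 ha     1 LIG   0.130000
     12 H6           1.7536    -0.0000    -2.1501 ha     1 LIG   0.130000
     13 O1          -0.5040     0.7117     1.2327 oh     1 LIG  -0.650000
     14 O2          -0.5040     0.7117    -1.2327 oh     1 LIG  -0.650000
     15 OG          -0.5040    -1.4234     0.0000 oh     1 LIG  -0.650000
     16 HO1         -1.4780     0.7117     1.2327 ho     1 LIG   0.420000
     17 HO2         -1.4780     0.7117    -1.2327 ho     1 LIG   0.420000
     18 CB          -1.8385    -1.4501     0.4546 2c     1 LIG   0.120000
     19 HB1         -2.4600    -0.8452    -0.2056 h1     1 LIG   0.060000
     20 HB2         -1.8862    -1.0484     1.4667 h1     1 LIG   0.060000
     21 CA          -2.5088    -2.7539    -0.0005 cx     1 LIG   0.050000
     22 HA1         -1.9675    -3.6049     0.4130 hc     1 LIG   0.030000
     23 HA2         -3.5404    -2.7746     0.3509 hc     1 LIG   0.030000
     24 HA3         -2.4951    -2.8094    -1.0890 hc     1 LIG   0.030000
@<TRIPOS>BOND
     1     1     2 1
     2     2     3 1
     3     3     4 1
     4     4     5 1
     5     5     6 1
     6     6     7 1
     7     3     8 1
     8     4     9 1
     9     5    10 1
    10     6    11 1
    11     7    12 1
    12     1    13 1
    13     1    14 1
    14     1    15 1
    15    13    16 1
    16    14    17 1
    17    15    18 1
    18    18    19 1
    19    18    20 1
    20    18    21 1
    21    21    22 1
    22    21    23 1
    23    21    24 1
    24     7     2 1
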