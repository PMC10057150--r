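# boronfit minimal topology: atom <index> <name> <type> <charge>; bond <i> <j> (1-based)
atom 1 B b 0.680000
atom 2 C1 ca -0.100000
atom 3 C2 ca -0.100000
atom 4 C3 ca -0.100000
atom 5 C4 ca -0.100000
atom 6 C5 ca -0.100000
atom 7 C6 ca -0.100000
atom 8 H2 ha 0.130000
atom 9 H3 ha 0.130000
atom 10 H4 ha 0.130000
atom 11 H5 ha 0.130000
atom 12 H6 ha 0.130000
atom 13 O1 oh -0.650000
atom 14 O2 oh -0.650000
atom 15 OG oh -0.650000
atom 16 HO1 ho 0.420000
atom 17 HO2 ho 0.420000
atom 18 CB 2c 0.120000
atom 19 HB1 h1 0.060000
atom 20 HB2 h1 0.060000
atom 21 CA cx 0.050000
atom 22 HA1 hc 0.030000
atom 23 HA2 hc 0.030000
atom 24 HA3 hc 0.030000
bond 1 2
bond 2 3
bond 3 4
bond 4 5
bond 5 6
bond 6 7
bond 3 8
bond 4 9
bond 5 10
bond 6 11
bond 7 12
bond 1 13
bond 1 14
bond 1 15
bond 13 16
bond 14 17
bond 15 18
bond 18 19
bond 18 20
bond 18 21
bond 21 22
bond 21 23
bond 21 24
bond 7 2
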