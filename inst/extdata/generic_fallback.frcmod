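boronfit generic sp2/sp3 fallback parameters (synthetic, idealized GAFF-style values)
BOND
ca-ca   469.00    1.400
ca-ha   367.00    1.080
c2-ha   367.00    1.080
c2-ca   427.00    1.430
c3-h1   340.00    1.090
c3-hc   340.00    1.090
c3-c3   303.00    1.535
c3-n3   320.00    1.470
c3-ca   323.50    1.510
n3-hn   394.10    1.010
oh-ho   369.60    0.974
o -ho   369.60    0.974
oh-2c   320.00    1.410
2c-h1   340.00    1.090
2c-cx   303.00    1.535
cx-hc   337.00    1.090
o -c3   320.00    1.410

ANGLE
ca-ca-ca   63.21   120.00
ca-ca-ha   48.46   120.00
c2-ca-ca   64.00   120.00
c3-ca-ca   63.84   120.00
ha-c2-ha   38.95   120.00
h1-c3-h1   39.18   109.50
h1-c3-n3   49.41   109.50
h1-c3-ca   46.80   109.50
n3-c3-ca   66.00   109.50
h1-c3-c3   46.37   109.50
o -c3-h1   50.84   109.50
o -c3-c3   67.78   109.50
c3-c3-hc   46.37   109.50
hc-c3-hc   39.43   109.50
hc-cx-hc   39.43   109.50
2c-cx-hc   46.37   109.50
oh-2c-h1   50.97   109.50
oh-2c-cx   67.72   109.50
h1-2c-h1   39.18   109.50
h1-2c-cx   46.37   109.50
c3-n3-hn   47.13   109.50
hn-n3-hn   41.30   109.50

DIHE
X -ca-ca-X    4    14.5000   180.0000    2.000
X -c2-ca-X    4     4.0000   180.0000    2.000
X -c3-ca-X    6     1.4000     0.0000    3.000
X -c3-n3-X    6     1.8000     0.0000    3.000
X -2c-cx-X    9     1.4000     0.0000    3.000
X -c3-c3-X    9     1.4000     0.0000    3.000

IMPROPER
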