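# label i j k l (1-based)
tau1 18 15 1 2
tau2 15 1 2 3
tau3 16 13 1 2
tau4 17 14 1 2
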