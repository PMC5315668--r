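ATOM      1  CA  UNK A   1       0.500   0.000   0.000  1.00  0.00           C
ATOM      2  CA  UNK A   2      -0.500   0.000   0.000  1.00  0.00           C
END
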