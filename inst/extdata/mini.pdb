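ATOM      1  CA  ALA A 114      10.000  10.000  10.000  1.00 15.00           C
ATOM      2  CA AALA A 115      13.800  10.000  10.000  0.40 20.00           C
ATOM      3  CA BALA A 115      13.900  10.100  10.000  0.60 22.00           C
ATOM      4  N   GLY A 116      17.000  10.000  10.000  1.00 18.00           N
ATOM      5  CA  GLY A 116      17.600  10.500  10.200  1.00 18.00           C
END
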