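ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C
ATOM      2  CA  ALA A   2       0.000   0.000   3.800  1.00  0.00           C
ATOM      3  CA  ALA A   3       0.000   0.000   7.600  1.00  0.00           C
ATOM      4  CA  ALA A   4       0.000   0.000  11.400  1.00  0.00           C
ATOM      5  CA  ALA A   5       0.000   0.000  15.200  1.00  0.00           C
ATOM      6  CA  ALA A   6       0.000   0.000  19.000  1.00  0.00           C
ATOM      7  CA  ALA A   7       0.000   0.000  22.800  1.00  0.00           C
ATOM      8  CA  ALA A   8       0.000   0.000  26.600  1.00  0.00           C
ATOM      9  CA  ALA A   9       0.000   0.000  30.400  1.00  0.00           C
ATOM     10  CA  ALA A  10       0.000   0.000  34.200  1.00  0.00           C
ATOM     11  CA  ALA A  11       0.000   0.000  38.000  1.00  0.00           C
ATOM     12  CA  ALA A  12       0.000   0.000  41.800  1.00  0.00           C
ATOM     13  CA  ALA A  13       0.000   0.000  45.600  1.00  0.00           C
ATOM     14  CA  ALA A  14       0.000   0.000  49.400  1.00  0.00           C
ATOM     15  CA  ALA A  15       0.000   0.000  53.200  1.00  0.00           C
ATOM     16  CA  ALA A  16       0.000   0.000  57.000  1.00  0.00           C
ATOM     17  CA  ALA A  17       0.000   0.000  60.800  1.00  0.00           C
ATOM     18  CA  ALA A  18       0.000   0.000  64.600  1.00  0.00           C
ATOM     19  CA  ALA A  19       0.000   0.000  68.400  1.00  0.00           C
ATOM     20  CA  ALA A  20       0.000   0.000  72.200  1.00  0.00           C
END
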