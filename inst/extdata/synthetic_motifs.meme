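MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.25000 C 0.25000 G 0.25000 T 0.25000

MOTIF E2F
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.040000 0.070000 0.090000 0.800000
 0.060000 0.050000 0.080000 0.810000
 0.050000 0.080000 0.060000 0.810000
 0.080000 0.620000 0.220000 0.080000
 0.070000 0.180000 0.680000 0.070000
 0.050000 0.720000 0.140000 0.090000
 0.040000 0.100000 0.800000 0.060000
 0.110000 0.640000 0.140000 0.110000

MOTIF DREF
letter-probability matrix: alength= 4 w= 8 nsites= 20 E= 0
 0.050000 0.060000 0.070000 0.820000
 0.800000 0.060000 0.060000 0.080000
 0.060000 0.070000 0.050000 0.820000
 0.070000 0.740000 0.110000 0.080000
 0.060000 0.120000 0.760000 0.060000
 0.780000 0.080000 0.070000 0.070000
 0.050000 0.090000 0.060000 0.800000
 0.400000 0.220000 0.180000 0.200000

MOTIF FOXJ2
letter-probability matrix: alength= 4 w= 10 nsites= 20 E= 0
 0.080000 0.100000 0.120000 0.700000
 0.100000 0.150000 0.650000 0.100000
 0.050000 0.060000 0.070000 0.820000
 0.040000 0.050000 0.060000 0.850000
 0.060000 0.070000 0.080000 0.790000
 0.550000 0.150000 0.150000 0.150000
 0.140000 0.580000 0.120000 0.160000
 0.100000 0.120000 0.140000 0.640000
 0.120000 0.140000 0.160000 0.580000
 0.150000 0.130000 0.120000 0.600000

MOTIF RAM
letter-probability matrix: alength= 4 w= 12 nsites= 20 E= 0
 0.100000 0.600000 0.150000 0.150000
 0.650000 0.100000 0.100000 0.150000
 0.120000 0.140000 0.600000 0.140000
 0.080000 0.700000 0.120000 0.100000
 0.100000 0.150000 0.620000 0.130000
 0.090000 0.160000 0.660000 0.090000
 0.120000 0.580000 0.140000 0.160000
 0.620000 0.120000 0.140000 0.120000
 0.100000 0.140000 0.160000 0.600000
 0.640000 0.120000 0.120000 0.120000
 0.580000 0.160000 0.120000 0.140000
 0.120000 0.620000 0.120000 0.140000
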