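# SYNTHETIC stand-in background for beta-barrel transmembrane strands.
# The published bbTM (TM-strand matrix) background vector is not
# redistributed here; this composition reflects typical residue frequencies
# of beta-barrel TM strands (aromatic-girdle and alternating polar pattern).
# Any 20-vector file in this format may be supplied instead via config.
A 0.080
R 0.030
N 0.040
D 0.030
C 0.005
Q 0.040
E 0.030
G 0.100
H 0.020
I 0.060
L 0.110
K 0.030
M 0.020
F 0.080
P 0.020
S 0.070
T 0.070
W 0.040
Y 0.075
V 0.050
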