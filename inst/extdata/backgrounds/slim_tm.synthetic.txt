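# SYNTHETIC stand-in background for alpha-helical transmembrane segments.
# The published SLIM substitution-model background vector is not
# redistributed here; this composition reflects typical residue frequencies
# of alpha-helical TM spans (Leu/Ile/Val/Phe/Ala-rich, charged-depleted).
# Any 20-vector file in this format may be supplied instead via config.
A 0.105
R 0.020
N 0.020
D 0.012
C 0.015
Q 0.015
E 0.014
G 0.072
H 0.012
I 0.105
L 0.160
K 0.015
M 0.035
F 0.090
P 0.025
S 0.050
T 0.050
W 0.030
Y 0.030
V 0.125
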