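# Solvent-accessible surface area of residues in an extended tripeptide,
# in units of 100 square angstroms (Rose et al. 1985, Science 229:834-838).
A 1.181
R 2.560
N 1.655
D 1.587
C 1.461
Q 1.932
E 1.862
G 0.881
H 2.025
I 1.810
L 1.931
K 2.258
M 2.034
F 2.228
P 1.468
S 1.298
T 1.525
W 2.663
Y 2.368
V 1.645
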