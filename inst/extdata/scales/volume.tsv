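# Volume of amino-acid side chains in cubic angstroms
# (after Chothia-type partial volumes; AAindex-style side-chain volumes).
A 27.5
R 105.0
N 58.7
D 40.0
C 44.6
Q 80.7
E 62.0
G 0.0
H 79.0
I 93.5
L 93.5
K 100.0
M 94.1
F 115.5
P 41.9
S 29.3
T 51.3
W 145.5
Y 117.3
V 71.5
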