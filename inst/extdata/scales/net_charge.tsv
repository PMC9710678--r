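# Net charge index of amino-acid side chains (NCI; Zhou et al. 2006-style
# table as commonly used with autocorrelation PPI descriptors).
A 0.007187
R 0.043587
N 0.005392
D -0.02382
C -0.03661
Q 0.049211
E 0.006802
G 0.179052
H -0.01069
I 0.021631
L 0.051672
K 0.017708
M 0.002683
F 0.037552
P 0.239531
S 0.004627
T 0.003352
W 0.037977
Y 0.023599
V 0.057004
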