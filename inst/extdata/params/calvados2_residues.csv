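# CALVADOS2 residue table: optimized lambda; sigma nm, mass g/mol, q in e
res,q,lambda,sigma,mass
A,0,0.2743,0.504,71.08
R,1,0.7307,0.656,156.19
N,0,0.4255,0.568,114.1
D,-1,0.0416,0.558,115.09
C,0,0.5615,0.548,103.14
Q,0,0.3934,0.602,128.13
E,-1,6e-04,0.592,129.12
G,0,0.7058,0.45,57.05
H,0,0.4663,0.608,137.14
I,0,0.5423,0.618,113.16
L,0,0.644,0.618,113.16
K,1,0.179,0.636,128.17
M,0,0.5308,0.618,131.19
F,0,0.8672,0.636,147.18
P,0,0.3593,0.556,97.12
S,0,0.4625,0.518,87.08
T,0,0.3713,0.562,101.1
W,0,0.9893,0.678,186.21
Y,0,0.9774,0.646,163.18
V,0,0.2083,0.586,99.07
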