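# HPS-Urry residue table: Urry hydropathy scale; sigma nm, mass g/mol, q in e
res,q,lambda,sigma,mass
A,0,0.603,0.504,71.08
R,1,0.559,0.656,156.19
N,0,0.589,0.568,114.1
D,-1,0.295,0.558,115.09
C,0,0.648,0.548,103.14
Q,0,0.549,0.602,128.13
E,-1,0,0.592,129.12
G,0,0.579,0.45,57.05
H,0,0.764,0.608,137.14
I,0,0.693,0.618,113.16
L,0,0.721,0.618,113.16
K,1,0.427,0.636,128.17
M,0,0.89,0.618,131.19
F,0,0.827,0.636,147.18
P,0,0.759,0.556,97.12
S,0,0.589,0.518,87.08
T,0,0.582,0.562,101.1
W,0,1,0.678,186.21
Y,0,0.896,0.646,163.18
V,0,0.664,0.586,99.07
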