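# Mpipi/Mpipi-Recharged residue table (lambda unused; pair table carries eps/sigma/nu)
res,q,lambda,sigma,mass
A,0,NA,0.504,71.08
R,1,NA,0.656,156.19
N,0,NA,0.568,114.1
D,-1,NA,0.558,115.09
C,0,NA,0.548,103.14
Q,0,NA,0.602,128.13
E,-1,NA,0.592,129.12
G,0,NA,0.45,57.05
H,0,NA,0.608,137.14
I,0,NA,0.618,113.16
L,0,NA,0.618,113.16
K,1,NA,0.636,128.17
M,0,NA,0.618,131.19
F,0,NA,0.636,147.18
P,0,NA,0.556,97.12
S,0,NA,0.518,87.08
T,0,NA,0.562,101.1
W,0,NA,0.678,186.21
Y,0,NA,0.646,163.18
V,0,NA,0.586,99.07
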