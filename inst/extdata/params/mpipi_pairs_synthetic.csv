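# SYNTHETIC Wang-Frenkel pair table for the Mpipi-family models.
# Surrogate values: preserve pair-specific structure and W>Y>F /
# cation-pi ranking of the published models, but are NOT the published
# numbers. eps kJ/mol, sigma nm, nu dimensionless.
i,j,eps,sigma,nu
A,A,0.27,0.504,1
A,R,0.3375,0.58,1
R,R,0.405,0.656,1
A,N,0.2925,0.536,1
R,N,0.36,0.612,1
N,N,0.315,0.568,1
A,D,0.2475,0.531,1
R,D,0.315,0.607,1
N,D,0.27,0.563,1
D,D,0.225,0.558,1
A,C,0.315,0.526,1
R,C,0.3825,0.602,1
N,C,0.3375,0.558,1
D,C,0.2925,0.553,1
C,C,0.36,0.548,1
A,Q,0.2925,0.553,1
R,Q,0.36,0.629,1
N,Q,0.315,0.585,1
D,Q,0.27,0.58,1
C,Q,0.3375,0.575,1
Q,Q,0.315,0.602,1
A,E,0.2475,0.548,1
R,E,0.315,0.624,1
N,E,0.27,0.58,1
D,E,0.225,0.575,1
C,E,0.2925,0.57,1
Q,E,0.27,0.597,1
E,E,0.225,0.592,1
A,G,0.27,0.477,1
R,G,0.3375,0.553,1
N,G,0.2925,0.509,1
D,G,0.2475,0.504,1
C,G,0.315,0.499,1
Q,G,0.2925,0.526,1
E,G,0.2475,0.521,1
G,G,0.27,0.45,1
A,H,0.3375,0.556,1
R,H,0.405,0.632,1
N,H,0.36,0.588,1
D,H,0.315,0.583,1
C,H,0.3825,0.578,1
Q,H,0.36,0.605,1
E,H,0.315,0.6,1
G,H,0.3375,0.529,1
H,H,0.405,0.608,1
A,I,0.36,0.561,1
R,I,0.4275,0.637,1
N,I,0.3825,0.593,1
D,I,0.3375,0.588,1
C,I,0.405,0.583,1
Q,I,0.3825,0.61,1
E,I,0.3375,0.605,1
G,I,0.36,0.534,1
H,I,0.4275,0.613,1
I,I,0.45,0.618,1
A,L,0.36,0.561,1
R,L,0.4275,0.637,1
N,L,0.3825,0.593,1
D,L,0.3375,0.588,1
C,L,0.405,0.583,1
Q,L,0.3825,0.61,1
E,L,0.3375,0.605,1
G,L,0.36,0.534,1
H,L,0.4275,0.613,1
I,L,0.45,0.618,1
L,L,0.45,0.618,1
A,K,0.27,0.57,1
R,K,0.3375,0.646,1
N,K,0.2925,0.602,1
D,K,0.2475,0.597,1
C,K,0.315,0.592,1
Q,K,0.2925,0.619,1
E,K,0.2475,0.614,1
G,K,0.27,0.543,1
H,K,0.3375,0.622,1
I,K,0.36,0.627,1
L,K,0.36,0.627,1
K,K,0.27,0.636,1
A,M,0.36,0.561,1
R,M,0.4275,0.637,1
N,M,0.3825,0.593,1
D,M,0.3375,0.588,1
C,M,0.405,0.583,1
Q,M,0.3825,0.61,1
E,M,0.3375,0.605,1
G,M,0.36,0.534,1
H,M,0.4275,0.613,1
I,M,0.45,0.618,1
L,M,0.45,0.618,1
K,M,0.36,0.627,1
M,M,0.45,0.618,1
A,F,0.3825,0.57,1
R,F,1.5525,0.646,2
N,F,0.405,0.602,1
D,F,0.36,0.597,1
C,F,0.4275,0.592,1
Q,F,0.405,0.619,1
E,F,0.36,0.614,1
G,F,0.3825,0.543,1
H,F,0.45,0.622,1
I,F,0.4725,0.627,1
L,F,0.4725,0.627,1
K,F,0.3825,0.636,2
M,F,0.4725,0.627,1
F,F,0.9021,0.636,2
A,P,0.315,0.53,1
R,P,0.3825,0.606,1
N,P,0.3375,0.562,1
D,P,0.2925,0.557,1
C,P,0.36,0.552,1
Q,P,0.3375,0.579,1
E,P,0.2925,0.574,1
G,P,0.315,0.503,1
H,P,0.3825,0.582,1
I,P,0.405,0.587,1
L,P,0.405,0.587,1
K,P,0.315,0.596,1
M,P,0.405,0.587,1
F,P,0.4275,0.596,1
P,P,0.36,0.556,1
A,S,0.27,0.511,1
R,S,0.3375,0.587,1
N,S,0.2925,0.543,1
D,S,0.2475,0.538,1
C,S,0.315,0.533,1
Q,S,0.2925,0.56,1
E,S,0.2475,0.555,1
G,S,0.27,0.484,1
H,S,0.3375,0.563,1
I,S,0.36,0.568,1
L,S,0.36,0.568,1
K,S,0.27,0.577,1
M,S,0.36,0.568,1
F,S,0.3825,0.577,1
P,S,0.315,0.537,1
S,S,0.27,0.518,1
A,T,0.279,0.533,1
R,T,0.3465,0.609,1
N,T,0.3015,0.565,1
D,T,0.2565,0.56,1
C,T,0.324,0.555,1
Q,T,0.3015,0.582,1
E,T,0.2565,0.577,1
G,T,0.279,0.506,1
H,T,0.3465,0.585,1
I,T,0.369,0.59,1
L,T,0.369,0.59,1
K,T,0.279,0.599,1
M,T,0.369,0.59,1
F,T,0.3915,0.599,1
P,T,0.324,0.559,1
S,T,0.279,0.54,1
T,T,0.288,0.562,1
A,W,0.4725,0.591,1
R,W,2.185,0.667,2
N,W,0.495,0.623,1
D,W,0.45,0.618,1
C,W,0.5175,0.613,1
Q,W,0.495,0.64,1
E,W,0.45,0.635,1
G,W,0.4725,0.564,1
H,W,0.54,0.643,1
I,W,0.5625,0.648,1
L,W,0.5625,0.648,1
K,W,0.4725,0.657,2
M,W,0.5625,0.648,1
F,W,1.5005,0.657,2
P,W,0.5175,0.617,1
S,W,0.4725,0.598,1
T,W,0.4815,0.62,1
W,W,2.4368,0.678,2
A,Y,0.4275,0.575,1
R,Y,1.84,0.651,2
N,Y,0.45,0.607,1
D,Y,0.405,0.602,1
C,Y,0.4725,0.597,1
Q,Y,0.45,0.624,1
E,Y,0.405,0.619,1
G,Y,0.4275,0.548,1
H,Y,0.495,0.627,1
I,Y,0.5175,0.632,1
L,Y,0.5175,0.632,1
K,Y,0.4275,0.641,2
M,Y,0.5175,0.632,1
F,Y,1.1664,0.641,2
P,Y,0.4725,0.601,1
S,Y,0.4275,0.582,1
T,Y,0.4365,0.604,1
W,Y,1.9152,0.662,2
Y,Y,1.4976,0.646,2
A,V,0.3375,0.545,1
R,V,0.405,0.621,1
N,V,0.36,0.577,1
D,V,0.315,0.572,1
C,V,0.3825,0.567,1
Q,V,0.36,0.594,1
E,V,0.315,0.589,1
G,V,0.3375,0.518,1
H,V,0.405,0.597,1
I,V,0.4275,0.602,1
L,V,0.4275,0.602,1
K,V,0.3375,0.611,1
M,V,0.4275,0.602,1
F,V,0.45,0.611,1
P,V,0.3825,0.571,1
S,V,0.3375,0.552,1
T,V,0.3465,0.574,1
W,V,0.54,0.632,1
Y,V,0.495,0.616,1
V,V,0.405,0.586,1
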