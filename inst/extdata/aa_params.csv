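code,lambda,sigma,charge,mass
A,0.72973,5.04,0,71.08
R,0,6.56,1,156.2
N,0.43243,5.68,0,114.1
D,0.37838,5.58,-1,115.1
C,0.59459,5.48,0,103.1
Q,0.51351,6.02,0,128.1
E,0.45946,5.92,-1,129.1
G,0.64865,4.5,0,57.05
H,0.51351,6.08,0,137.1
I,0.97297,6.18,0,113.2
L,0.97297,6.18,0,113.2
K,0.51351,6.36,1,128.2
M,0.83784,6.18,0,131.2
F,1,6.36,0,147.2
P,1,5.56,0,97.12
S,0.59459,5.18,0,87.08
T,0.67568,5.62,0,101.1
W,0.94595,6.78,0,186.2
Y,0.86486,6.46,0,163.2
V,0.89189,5.86,0,99.07
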