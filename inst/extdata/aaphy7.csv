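,steric,hydrophobicity,volume,polarizability,isoelectric,helix,sheet
A,1.28,0.31,1,0.05,6.11,0.42,0.23
R,2.34,-1.01,6.13,0.29,10.74,0.36,0.25
N,1.6,-0.6,2.95,0.13,6.52,0.21,0.22
D,1.6,-0.77,2.78,0.11,2.95,0.25,0.2
C,1.77,1.54,2.43,0.13,6.35,0.17,0.41
Q,1.56,-0.22,3.95,0.18,5.65,0.36,0.25
E,1.56,-0.64,3.78,0.15,3.09,0.42,0.21
G,0,0,0,0,6.07,0.13,0.15
H,2.99,0.13,4.66,0.23,7.69,0.27,0.3
I,4.19,1.8,4,0.19,6.04,0.3,0.45
L,2.59,1.7,4,0.19,6.04,0.39,0.31
K,1.89,-0.99,4.77,0.22,9.99,0.32,0.27
M,2.35,1.23,4.43,0.22,5.71,0.38,0.32
F,2.94,1.79,5.89,0.29,5.67,0.3,0.38
P,2.67,0.72,2.72,0,6.8,0.13,0.34
S,1.31,-0.04,1.6,0.06,5.7,0.2,0.28
T,3.03,0.26,2.6,0.11,5.6,0.21,0.36
W,3.21,2.25,8.08,0.41,5.94,0.32,0.42
Y,2.94,0.96,6.47,0.3,5.66,0.25,0.41
V,3.67,1.22,3,0.14,6.02,0.27,0.49
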