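site,year,p,p_lower,p_upper,psi,psi_lower,psi_upper,lambda,lambda_lower,lambda_upper
A,2015,0.23,0.13,0.36,0.69,0.33,0.91,0.67,0,3
B,2014,0.32,0.22,0.44,0.82,0.50,0.96,0.47,0,2
C,2014,0.38,0.27,0.50,0.83,0.51,0.96,2.94,2,5
C,2015,0.64,0.43,0.81,0.89,0.64,0.97,7.94,5,11
D,2014,0.29,0.19,0.41,0.72,0.36,0.92,0.27,0,2
E,2014,0.22,0.13,0.36,0.46,0.16,0.80,0.09,0,1
F,2014,0.55,0.38,0.71,0.87,0.59,0.97,5.44,4,8
F,2015,0.92,0.62,0.99,0.94,0.76,0.99,8.06,5,12
G,2014,0.30,0.20,0.43,0.76,0.41,0.94,1.33,1,3
H,2014,0.24,0.14,0.37,0.78,0.43,0.94,0.35,0,2
I,2015,0.25,0.15,0.38,0.58,0.23,0.86,0.33,0,2
J,2014,0.26,0.17,0.39,0.63,0.27,0.89,1.54,1,3
J,2015,0.36,0.25,0.48,0.79,0.45,0.95,4.14,2,7
K,2014,0.23,0.14,0.37,0.68,0.32,0.91,0.22,0,1
L,2014,0.32,0.22,0.44,0.82,0.50,0.96,1.79,1,4
L,2015,0.24,0.14,0.37,0.53,0.19,0.84,1.18,1,2
M,2014,0.18,0.09,0.33,0.18,0.04,0.50,1.08,1,2
M,2015,0.20,0.10,0.34,0.25,0.07,0.61,1.07,1,2
N,2014,0.22,0.13,0.36,0.56,0.21,0.85,0.13,0,1
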