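Gamma: 100.0
R_gas: 8.31400000000000006
T_abs: 310.0
mu: 0.0007
sigma: 1.0
Ind_max: 33.0
Ind_C50: 8.99999999999999921e-05
f_u_inc: 0.40000000000000002
Ka: 2300000.0
L_S: 6.99999999999999939e-05
L_C: 3.00000000000000008e-05
alpha: 0.29999999999999999
u_RPE: 2.29999999999999995e-07
p_orbit: 399.96600000000000819
dP_blood: 666.61000000000001364
dP_SCS: 133.32200000000000273
EVP: 999.91499999999996362
Q_prod: 8.00000000000000024e-13
C_fac: 7.37562692828890416e-16
Lp_star: 3.5599999999999998e-05
K_S: 6.39999999999999984e-18
K_C: 6.39999999999999947e-16
D2_S: 9.59999999999999948e-12
D3_S: 9.59999999999999948e-12
D2_C: 8.74999999999999951e-11
D3_C: 8.74999999999999951e-11
beta: 0.00137
c_SA_blood_total: 0.40999999999999998
c3_B: 0.01167
k_prod: 7.7999999999999997e-08
k_CYP_deg: 0.00035
A_S: 3.19999999999999986e-05
species: mouse
condition: feeding
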