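Gamma: 100.0
R_gas: 8.31400000000000006
T_abs: 310.0
mu: 0.0007
sigma: 1.0
Ind_max: 33.0
Ind_C50: 8.99999999999999921e-05
f_u_inc: 0.40000000000000002
Ka: 2300000.0
L_S: 0.00067
L_C: 0.000268
alpha: 0.034
u_RPE: 2.99999999999999973e-08
p_orbit: 399.96600000000000819
dP_blood: 666.61000000000001364
dP_SCS: 133.32200000000000273
EVP: 946.58619999999996253
Q_prod: 4.21666666666666632e-11
C_fac: 3.25027627348324609e-14
Lp_star: 1.83000000000000011e-07
K_S: 1.33000000000000005e-18
K_C: 1.33000000000000016e-16
D2_S: 9.59999999999999948e-12
D3_S: 9.59999999999999948e-12
D2_C: 8.74999999999999951e-11
D3_C: 8.74999999999999951e-11
beta: 3.40000000000000006e-06
c_SA_blood_total: 0.68000000000000005
c3_B: 2.5000000000000002e-06
k_prod: 1.00999999999999995e-08
k_CYP_deg: 4.55999999999999971e-05
A_S: 0.00149
species: human
condition: control
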