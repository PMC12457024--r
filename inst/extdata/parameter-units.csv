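symbol,unit,category
L_C,m,well-known
L_S,m,well-known
alpha,1,somewhat-known
Gamma,1,well-known
R_gas,J mol-1 K-1,well-known
T_abs,K,well-known
mu,Pa s,well-known
u_RPE,m s-1,somewhat-known
p_orbit,Pa,well-known
dP_blood,Pa,somewhat-known
dP_SCS,Pa,somewhat-known
EVP,Pa,well-known
Q_prod,m3 s-1,well-known
C_fac,m3 s-1 Pa-1,well-known
Lp_star,s-1 Pa-1,extremely-uncertain
K_S,m2,somewhat-known
K_C,m2,somewhat-known
D2_S,m2 s-1,well-known
D3_S,m2 s-1,well-known
D2_C,m2 s-1,well-known
D3_C,m2 s-1,well-known
beta,s-1,extremely-uncertain
c_SA_blood_total,mol m-3,well-known
c3_B,mol m-3,well-known
sigma,1,well-known
k_prod,mol m-3 s-1,extremely-uncertain
k_CYP_deg,s-1,extremely-uncertain
Ind_max,1,somewhat-known
Ind_C50,mol m-3,somewhat-known
f_u_inc,1,somewhat-known
A_S,m2,well-known
Ka,M-1,somewhat-known
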