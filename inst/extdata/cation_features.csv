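symbol,charge,atomic_number,melting_point_k,heat_capacity_j_mol_k,ionic_radius_pm,polarizability_a3,electron_affinity_ev,electronegativity
Li,1,3,453.7,24.86,76,24.3,0.618,0.98
Na,1,11,371.0,28.23,102,24.1,0.548,0.93
K,1,19,336.5,29.60,138,43.4,0.501,0.82
Rb,1,37,312.5,31.06,152,47.3,0.486,0.82
Cs,1,55,301.6,32.21,167,59.4,0.472,0.79
Cu,1,29,1357.8,24.44,77,6.2,1.236,1.90
Ag,1,47,1234.9,25.35,115,7.2,1.302,1.93
Tl,1,81,577.0,26.32,150,7.6,0.377,1.62
Be,2,4,1560.0,16.44,45,5.6,0.0,1.57
Mg,2,12,923.0,24.87,72,10.6,0.0,1.31
Ca,2,20,1115.0,25.93,100,22.8,0.0246,1.00
Sr,2,38,1050.0,26.40,118,27.6,0.052,0.95
Ba,2,56,1000.0,28.07,135,39.7,0.145,0.89
Mn,2,25,1519.0,26.32,83,9.4,0.0,1.55
Fe,2,26,1811.0,25.10,78,8.4,0.151,1.83
Co,2,27,1768.0,24.81,74.5,7.5,0.662,1.88
Ni,2,28,1728.0,26.07,69,6.8,1.156,1.91
Cu,2,29,1357.8,24.44,73,6.2,1.236,1.90
Zn,2,30,692.7,25.39,74,5.75,0.0,1.65
Cd,2,48,594.2,26.02,95,7.36,0.0,1.69
Hg,2,80,234.3,27.98,102,5.02,0.0,2.00
Pd,2,46,1828.0,25.98,86,4.8,0.562,2.20
Pt,2,78,2041.0,25.86,80,6.5,2.128,2.28
Pb,2,82,600.6,26.65,119,6.98,0.356,2.33
Sn,2,50,505.1,27.11,112,7.7,1.112,1.96
Eu,2,63,1099.0,27.66,117,27.7,0.116,1.20
Al,3,13,933.5,24.20,53.5,6.8,0.433,1.61
Ga,3,31,302.9,25.86,62,8.12,0.43,1.81
In,3,49,429.7,26.74,80,10.2,0.30,1.78
Tl,3,81,577.0,26.32,88.5,7.6,0.377,1.62
Bi,3,83,544.6,25.52,103,7.4,0.942,2.02
Sb,3,51,903.8,25.23,76,6.6,1.046,2.05
Sc,3,21,1814.0,25.52,74.5,17.8,0.188,1.36
Y,3,39,1799.0,26.53,90,22.7,0.307,1.22
Ti,3,22,1941.0,25.06,67,14.6,0.079,1.54
V,3,23,2183.0,24.89,64,12.4,0.525,1.63
Cr,3,24,2180.0,23.35,61.5,11.6,0.666,1.66
Fe,3,26,1811.0,25.10,64.5,8.4,0.151,1.83
La,3,57,1193.0,27.11,103.2,31.1,0.47,1.10
Ce,3,58,1068.0,26.94,101,29.6,0.57,1.12
Pr,3,59,1208.0,27.20,99,28.2,0.109,1.13
Nd,3,60,1297.0,27.45,98.3,31.4,0.097,1.14
Sm,3,62,1345.0,29.54,95.8,28.8,0.162,1.17
Eu,3,63,1099.0,27.66,94.7,27.7,0.116,1.20
Gd,3,64,1585.0,37.03,93.8,23.5,0.137,1.20
Tb,3,65,1629.0,28.91,92.3,25.5,0.436,1.20
Dy,3,66,1680.0,27.70,91.2,24.5,0.352,1.22
Ho,3,67,1734.0,27.15,90.1,23.6,0.338,1.23
Er,3,68,1802.0,28.12,89,22.7,0.312,1.24
Tm,3,69,1818.0,27.03,88,21.8,1.029,1.25
Yb,3,70,1097.0,26.74,86.8,21.0,0.020,1.10
Lu,3,71,1925.0,26.86,86.1,21.9,0.346,1.27
Th,4,90,2023.0,26.23,94,32.1,0.368,1.30
U,4,92,1405.0,27.66,89,24.9,0.315,1.38
Zr,4,40,2128.0,25.36,72,17.9,0.426,1.33
Hf,4,72,2506.0,25.73,71,16.2,0.017,1.30
Ce,4,58,1068.0,26.94,87,29.6,0.57,1.12
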