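target,name,R_TpiPCTPC,nRing,ATSC4m,GATS3p,fragC,MATS7e,MAXDP,AATS3e,SIC0,GATS7m,SpMax1_Bhv,JGT,apol,SpMin2_Bhv,ATSC6p,AATSC8p,pic50_pred,ic50_molar,mw,ic50_ugml
PTP1B,Diosmetin,7.249,3,24.31,1.084,114.06,-0.043,5.124,8.299,,,,,,,,,4.955,1.11E-05,300.26,3.33
PTP1B,Q37DG,3.939,5,-120.67,1.021,412.17,0.014,6.737,8.565,,,,,,,,,6.213,6.12E-07,626.50,0.38
PTP1B,Q7G,4.419,4,-135.32,1.071,240.12,0.086,5.654,8.513,,,,,,,,,5.531,2.95E-06,464.40,1.37
PTP1B,Rutin,3.673,5,-137.09,1.055,403.16,0.028,6.570,8.544,,,,,,,,,5.273,5.33E-06,610.50,3.26
PTP1B,Cadinene,1.994,2,-390.42,1.254,46.00,-0.364,0.500,7.141,,,,,,,,,5.978,1.05E-06,204.35,0.21
PTP1B,Piperitol,3.251,5,-495.29,1.212,250.06,-0.104,3.820,7.818,,,,,,,,,5.146,7.14E-06,356.40,2.55
DPP4,Diosmetin,,,,,,,,,0.292,0.970,3.913,0.538,40.97,1.891,2.007,-0.046,5.398,4.00E-06,300.26,1.20
DPP4,Q37DG,,,,,,,,,0.249,0.855,3.984,0.556,81.16,1.899,3.257,-0.003,8.081,8.30E-09,626.50,0.01
DPP4,Q7G,,,,,,,,,0.268,0.824,3.935,0.561,60.59,1.911,1.380,-0.002,6.449,3.56E-07,464.40,0.17
DPP4,Rutin,,,,,,,,,0.248,0.888,3.896,0.565,80.36,1.909,0.918,-0.021,7.046,9.00E-08,610.50,0.05
DPP4,Cadinene,,,,,,,,,0.182,1.253,3.867,0.492,42.40,1.745,-0.405,0.109,8.540,2.88E-09,204.35,0.00
DPP4,Piperitol,,,,,,,,,0.259,1.088,3.899,0.407,53.35,1.928,-2.051,-0.048,4.828,1.48E-05,356.40,5.29
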