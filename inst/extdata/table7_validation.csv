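section,parameter,ptp1b,dpp4,threshold,comment
Internal validation,SEE,0.219,0.202,,
Internal validation,r2,0.880,0.952,>0.6,Passed
Internal validation,r2_adjusted,0.877,0.948,>0.6,Passed
Internal validation,PRESS,15.409,206.871,,
Leave-one-out (LOO) result,Q2,0.873,0.942,>0.6,Passed
Leave-one-out (LOO) result,avg_rm2_loo,0.829,0.919,>0.6,Passed
Leave-one-out (LOO) result,delta_rm2_loo,0.082,0.035,,
External validation (without scaling),r2,0.867,0.949,>0.6,Passed
External validation (without scaling),r0_2,0.862,0.940,>0.6,Passed
External validation (without scaling),r0_prime_2,0.814,0.923,>0.6,Passed
External validation (without scaling),RMSEP,0.206,0.257,,
External validation (without scaling),Q2_f1,0.863,0.942,>0.6,Passed
External validation (without scaling),Q2_f2,0.862,0.938,>0.6,Passed
External validation (after scaling),avg_rm2_test,0.769,0.818,>0.6,Passed
External validation (after scaling),delta_rm2_test,0.100,0.057,,
Error-based judgement,MAE_95,0.156,0.198,,
Error-based judgement,SD_95,0.102,0.112,,
Error-based judgement,MAE_verdict,GOOD,GOOD,,
Golbraikh and Tropsha,Q2,0.873,0.942,>0.5,Passed
Golbraikh and Tropsha,r2,0.867,0.949,>0.6,Passed
Golbraikh and Tropsha,abs_r02_minus_r0prime2,0.047,0.017,<0.3,Passed
Golbraikh and Tropsha,k,1.001,0.992,0.85 < k < 1.15,Passed
Golbraikh and Tropsha,ratio_r2_r02,0.006,0.001,<0.1,Passed
Golbraikh and Tropsha,k_prime,0.998,1.006,0.85 < k' < 1.15,Passed
Golbraikh and Tropsha,ratio_r2_r0prime2,0.061,0.028,<0.1,Passed
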