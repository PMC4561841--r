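model,n_params,delta_aic,loglik
"distance, srr_bet, pratio_at, PC_stepping-stone_at",4,0,-6.04
"distance, srr_bet, pratio_at, pratio_bet, PC_stepping-stone_at",5,0.70,-5.39
"distance, srr_bet, pratio_at, cti_at, PC_stepping-stone_at",5,0.92,-5.51
"distance, srr_bet, pratio_bet, pratio_at, cti_at, PC_stepping-stone_at",6,1.62,-4.85
"distance, pratio_bet, pratio_at, PC_stepping-stone_at",4,1.70,-6.89
"srr_bet",1,1.81,-9.47
"pratio_at",1,1.92,-8.20
"distance",1,2.73,-9.47
"pratio_bet",1,2.96,-8.59
"cti_at",1,3.70,-6.96
"PC_stepping-stone_at",1,9.33,-11.77
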