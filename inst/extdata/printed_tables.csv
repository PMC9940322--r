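state,condition,max_count,bc_count,both_count,printed_kappa_pct,printed_sens_max,printed_sens_bc,printed_prev_max_per100,printed_prev_bc_per100,denominator_policy,reproducible
FL,NICU,20548,17524,11185,55.7,0.64,0.54,7.40,6.31,reconstructed_from_max_prev,TRUE
FL,RDS,14673,2933,1450,15.7,0.49,0.10,2.72,0.54,state_total,TRUE
FL,SEIZURE,1236,85,56,8.4,0.66,0.05,0.24,0.02,state_total,FALSE
FL,AV,6933,17039,1932,14.5,0.11,0.28,1.27,3.14,state_total,FALSE
FL,BIRTH_INJURY,8311,333,73,1.5,0.22,0.01,1.54,0.06,state_total,FALSE
TX,NICU,62258,42592,34577,62.8,0.81,0.56,10.00,7.05,reconstructed_from_bc_prev,TRUE
TX,RDS,17897,3276,2100,18.6,0.64,0.12,4.74,0.87,reconstructed_from_max_prev,TRUE
TX,SEIZURE,2531,239,143,10.2,0.60,0.06,0.25,0.02,shared_sub_cohort,TRUE
TX,AV,23311,50969,6900,15.8,0.14,0.30,2.37,5.19,state_total,TRUE
TX,BIRTH_INJURY,11427,312,101,1.6,0.32,0.01,1.89,0.05,reconstructed_from_max_prev,TRUE
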