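name,n_states,k1,k2,k3,k4,k5,k6,k7,k8,k1_second_order,S_conc,k_last_second_order,P_conc,class,evo_distance
two_state_fast,2,1000,10,50,0.01,,,,,1000000,0.001,10,0.001,specialist,0.45000000000000001
three_state_wt,3,100,1,50,2,10,0.001,,,100000,0.001,,,specialist,0.81000000000000005
four_state_wt,4,200,5,80,4,120,2,30,0.01,200000,0.001,,,generalist,1.1499999999999999
backward_driven,3,0.5,40,2,30,1,10,,,500,0.001,,,mutant,
equilibrium_cycle,3,10,2,4,20,5,5,,,10000,0.001,,,unknown,
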