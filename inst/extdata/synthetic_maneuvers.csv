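subject_id,maneuver_index,target_flow_ml_s,achieved_flow_ml_s,feno_ppb
sim00001,1,30,,23.592303888334563
sim00001,2,30,,30.356009661140678
sim00001,3,50,,16.333020593063534
sim00001,4,50,,15.632098882037123
sim00001,5,100,,10.038340118642076
sim00001,6,100,,10.135699363110044
sim00001,7,300,,4.5821383787672021
sim00001,8,300,,4.6404345240099332
sim00002,1,30,,28.307388899693837
sim00002,2,30,,23.683140886035531
sim00002,3,50,,18.32561407887999
sim00002,4,50,,16.357353906138052
sim00002,5,100,,9.1698822492099623
sim00002,6,100,,9.7762721316270511
sim00002,7,300,,3.8196517168085502
sim00002,8,300,,4.7301899061092811
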