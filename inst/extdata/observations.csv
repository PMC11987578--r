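obs_id,facility_id,weight,item_q1,item_q2,item_q3
o1,f1,1.0,1,0,1
o2,f2,2.0,1,1,
o3,f2,1.0,0,0,1
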