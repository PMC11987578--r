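woman_id,weight,cluster_id,design_stratum,geo_domain,any_anc,n_visits,sources,recv_tt,recv_ifa,recv_bp
w1,1.2,c1,s1,r1,TRUE,4,hc,1,0,1
w2,0.8,c1,s1,r1,TRUE,,hosp;th,1,,0
w3,1.5,c2,s1,r2,FALSE,,,0,0,
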