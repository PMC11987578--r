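facility_id,weight,geo_domain,facility_category,offers_anc,item_a,item_b,item_c,train_t
f1,2.0,r1,hospital,TRUE,1,1,0,0.5
f2,1.0,r1,health_centre,TRUE,1,,0,0.25
f3,1.0,r2,health_centre,TRUE,0,1,1,1
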