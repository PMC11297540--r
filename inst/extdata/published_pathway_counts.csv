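status,variable,level,quintile,n
asymptomatic,diagnosed_on_index,no,1,1890
asymptomatic,diagnosed_on_index,no,2,2269
asymptomatic,diagnosed_on_index,no,3,2278
asymptomatic,diagnosed_on_index,no,4,2178
asymptomatic,diagnosed_on_index,no,5,2187
asymptomatic,diagnosed_on_index,yes,1,95
asymptomatic,diagnosed_on_index,yes,2,117
asymptomatic,diagnosed_on_index,yes,3,99
asymptomatic,diagnosed_on_index,yes,4,131
asymptomatic,diagnosed_on_index,yes,5,134
symptomatic,diagnosed_on_index,no,1,10141
symptomatic,diagnosed_on_index,no,2,10254
symptomatic,diagnosed_on_index,no,3,9634
symptomatic,diagnosed_on_index,no,4,9335
symptomatic,diagnosed_on_index,no,5,9320
symptomatic,diagnosed_on_index,yes,1,934
symptomatic,diagnosed_on_index,yes,2,862
symptomatic,diagnosed_on_index,yes,3,797
symptomatic,diagnosed_on_index,yes,4,793
symptomatic,diagnosed_on_index,yes,5,855
asymptomatic,referring_first_contact,no,1,1756
asymptomatic,referring_first_contact,no,2,2075
asymptomatic,referring_first_contact,no,3,2083
asymptomatic,referring_first_contact,no,4,1994
asymptomatic,referring_first_contact,no,5,1994
asymptomatic,referring_first_contact,yes,1,229
asymptomatic,referring_first_contact,yes,2,311
asymptomatic,referring_first_contact,yes,3,294
asymptomatic,referring_first_contact,yes,4,315
asymptomatic,referring_first_contact,yes,5,327
symptomatic,referring_first_contact,no,1,9538
symptomatic,referring_first_contact,no,2,9501
symptomatic,referring_first_contact,no,3,8884
symptomatic,referring_first_contact,no,4,8548
symptomatic,referring_first_contact,no,5,8520
symptomatic,referring_first_contact,yes,1,1537
symptomatic,referring_first_contact,yes,2,1615
symptomatic,referring_first_contact,yes,3,1547
symptomatic,referring_first_contact,yes,4,1580
symptomatic,referring_first_contact,yes,5,1655
asymptomatic,ed_at_index,no,1,1985
asymptomatic,ed_at_index,no,2,2386
asymptomatic,ed_at_index,no,3,2377
asymptomatic,ed_at_index,no,4,2309
asymptomatic,ed_at_index,no,5,2321
asymptomatic,ed_at_index,yes,1,0
asymptomatic,ed_at_index,yes,2,0
asymptomatic,ed_at_index,yes,3,0
asymptomatic,ed_at_index,yes,4,0
asymptomatic,ed_at_index,yes,5,0
symptomatic,ed_at_index,no,1,7177
symptomatic,ed_at_index,no,2,7476
symptomatic,ed_at_index,no,3,7023
symptomatic,ed_at_index,no,4,6926
symptomatic,ed_at_index,no,5,7117
symptomatic,ed_at_index,yes,1,3898
symptomatic,ed_at_index,yes,2,3640
symptomatic,ed_at_index,yes,3,3408
symptomatic,ed_at_index,yes,4,3202
symptomatic,ed_at_index,yes,5,3058
asymptomatic,lower_gi_scope,0,1,324
asymptomatic,lower_gi_scope,0,2,405
asymptomatic,lower_gi_scope,0,3,395
asymptomatic,lower_gi_scope,0,4,362
asymptomatic,lower_gi_scope,0,5,367
asymptomatic,lower_gi_scope,1+,1,1661
asymptomatic,lower_gi_scope,1+,2,1981
asymptomatic,lower_gi_scope,1+,3,1982
asymptomatic,lower_gi_scope,1+,4,1947
asymptomatic,lower_gi_scope,1+,5,1954
symptomatic,lower_gi_scope,0,1,4451
symptomatic,lower_gi_scope,0,2,4286
symptomatic,lower_gi_scope,0,3,3923
symptomatic,lower_gi_scope,0,4,3866
symptomatic,lower_gi_scope,0,5,3788
symptomatic,lower_gi_scope,1+,1,6624
symptomatic,lower_gi_scope,1+,2,6830
symptomatic,lower_gi_scope,1+,3,6508
symptomatic,lower_gi_scope,1+,4,6262
symptomatic,lower_gi_scope,1+,5,6387
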