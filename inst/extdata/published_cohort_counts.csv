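variable,level,quintile,n
age_group,<=50,1,840
age_group,<=50,2,837
age_group,<=50,3,869
age_group,<=50,4,932
age_group,<=50,5,916
age_group,51-60,1,1767
age_group,51-60,2,1714
age_group,51-60,3,1849
age_group,51-60,4,1816
age_group,51-60,5,1872
age_group,61-70,1,2963
age_group,61-70,2,3195
age_group,61-70,3,3095
age_group,61-70,4,3072
age_group,61-70,5,3111
age_group,71-80,1,3867
age_group,71-80,2,4061
age_group,71-80,3,3738
age_group,71-80,4,3615
age_group,71-80,5,3465
age_group,>80,1,3623
age_group,>80,2,3695
age_group,>80,3,3257
age_group,>80,4,3002
age_group,>80,5,3132
sex,female,1,6671
sex,female,2,6659
sex,female,3,6218
sex,female,4,5853
sex,female,5,5969
sex,male,1,6389
sex,male,2,6843
sex,male,3,6590
sex,male,4,6584
sex,male,5,6527
rural,rio_lt_45,1,11903
rural,rio_lt_45,2,12421
rural,rio_lt_45,3,11881
rural,rio_lt_45,4,11679
rural,rio_lt_45,5,11748
rural,rio_ge_45,1,1157
rural,rio_ge_45,2,1081
rural,rio_ge_45,3,927
rural,rio_ge_45,4,758
rural,rio_ge_45,5,748
elixhauser,lt_4,1,10913
elixhauser,lt_4,2,11511
elixhauser,lt_4,3,11012
elixhauser,lt_4,4,10960
elixhauser,lt_4,5,11039
elixhauser,ge_4,1,2147
elixhauser,ge_4,2,1991
elixhauser,ge_4,3,1796
elixhauser,ge_4,4,1477
elixhauser,ge_4,5,1457
histology,other,1,348
histology,other,2,382
histology,other,3,375
histology,other,4,357
histology,other,5,396
histology,adenocarcinoma,1,12712
histology,adenocarcinoma,2,13120
histology,adenocarcinoma,3,12433
histology,adenocarcinoma,4,12080
histology,adenocarcinoma,5,12100
stage,I,1,2268
stage,I,2,2517
stage,I,3,2460
stage,I,4,2416
stage,I,5,2465
stage,II,1,3309
stage,II,2,3404
stage,II,3,3158
stage,II,4,3064
stage,II,5,3127
stage,III,1,3194
stage,III,2,3230
stage,III,3,3077
stage,III,4,3020
stage,III,5,2992
stage,IV,1,2290
stage,IV,2,2298
stage,IV,3,2232
stage,IV,4,2198
stage,IV,5,2175
stage,unknown,1,1999
stage,unknown,2,2053
stage,unknown,3,1881
stage,unknown,4,1739
stage,unknown,5,1737
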