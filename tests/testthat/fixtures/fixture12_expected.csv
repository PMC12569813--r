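reference_id,n,W,U,Mc,S,CI,contribution
t01, 4, 0.00000000000000000,0.25000000000000000,0.37750000000000000,0.50000000000000000, 0.351699364426139971,1.31496826351132490
t02, 5, 0.25000000000000000,0.59999999999999998,0.48166666666666669,0.39999999999999997, 0.761159331763048286,1.32550881074285765
t03, 6, 0.25000000000000000,0.00000000000000000,0.47193877551020413,0.44444444444444442, 0.116767379021206943,4.37198509490167542
t04, 5, 0.75000000000000000,0.80000000000000004,0.37111111111111117,0.13333333333333333, 2.887554498713980955,0.34344265947920566
t05, 5, 0.25000000000000000,0.40000000000000002,0.54000000000000004,0.26666666666666666, 0.492386782788085009,1.47138501901582530
t06, 6, 0.50000000000000000,0.83333333333333337,0.56632653061224492,0.00000000000000000,15.369486751088938803,0.31502341997733907
t07, 4, 0.75000000000000000,0.00000000000000000,0.37750000000000000,0.33333333333333331, 0.040141014087312403,3.02000446193751815
t08, 4, 0.75000000000000000,0.75000000000000000,0.56625000000000003,0.16666666666666666, 1.505508647934312050,0.65981198263506613
t09, 4, 0.75000000000000000,0.25000000000000000,0.75500000000000000,0.25000000000000000, 0.724504614741712349,2.17722938422683043
t10, 2, 0.75000000000000000,1.00000000000000000,0.88888888888888884,0.00000000000000000,11.078755939868431213,0.15785765122678205
.summary,10, 0.50000000000000000,0.48833333333333334,0.53961819727891158,0.24944444444444444, 3.332796432443316803,1.51572167476544251
.deltas,NA, 0.11006979603869538,0.34018377386348103,0.16084160301923572,0.16600702796367789, 5.098772562213158999,                 NA
.H_d,NA,13.63333333333333286,                 NA,                 NA,                 NA,                   NA,                 NA
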