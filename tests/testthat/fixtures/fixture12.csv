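# radius_m: 10
# slope_deg: 0
# aspect: N
# buffer_width_m: 2
# survey_year: 2022
id,species,x,y,dbh,height,crown_width,crown_length,age,rel_elev,alive,origin
t01,pinus_yunnanensis,0,0,20,12,4,3,40,0.5,TRUE,original
t02,pinus_yunnanensis,3,1,15,10,3,2.5,30,0.8,TRUE,original
t03,quercus_acutissima,-2,3,25,14,5,4,45,1.2,TRUE,original
t04,betula_alnoides,1,-3.5,10,8,2.5,2,20,0.3,TRUE,original
t05,pinus_yunnanensis,-4,-2,18,11,3.5,3,35,0.9,TRUE,original
t06,camellia_sinensis,4,4,8,5,2,1.5,15,1.5,TRUE,original
t07,pinus_yunnanensis,6,-1,22,13,4.5,3.5,42,0.2,TRUE,original
t08,quercus_acutissima,-6,2,12,9,2.8,2.2,24,1.1,TRUE,original
t09,pinus_yunnanensis,-1,6,16,10.5,3.2,2.7,32,1.8,TRUE,original
t10,vaccinium_bracteatum,2,7,6,3,1.5,1.2,12,2,TRUE,original
t11,pinus_yunnanensis,8.5,3,14,9.5,3,2.4,28,0.6,TRUE,original
t12,betula_alnoides,-7,-5,9,7,2.2,1.8,18,0.4,TRUE,original
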