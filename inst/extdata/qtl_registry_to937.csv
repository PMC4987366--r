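trait,qtl,chr,cm_interval,mb_interval,n_locations,pct_diff
FW,fw1.1,1,57-75,74-78,3,-25
FW,fw1.2,1,77-128,78-90,2,-17
FW,fw2.1,2,47-69,38-40,2,-25
FW,fw2.2,2,69-138,42-50,3,-19
FW,fw3.1,3,51-111,7-58,3,-27
FW,fw3.2,3,111-124,58-62,2,-24
FW,fw4.1,4,0-30,0-4,2,-13
FW,fw4.2,4,30-135,4-62,2,-18
FW,fw7.1,7,39-77,60-64,2,-19
FW,fw10.1,10,0-84,0-61,2,-23
FW,fw11.1,11,69-93,49-50,2,-17
FW,fw12.1,12,94-133,62-65,2,20
CIR,cir2.1,2,69-86,36-42,2,-26
CIR,cir6.1,6,17-56,3-35,3,43
CIR,cir10.1,10,104-115,64-65,3,41
FS,fs4.1,4,41-94,3-35,2,6
FS,fs6.1,6,17-56,3-35,3,-7
FS,fs10.1,10,104-115,64-65,2,-6
PSH,psh1.1,1,50-135,3.8-70,3,-43
PSH,psh3.1,3,11-124,58-62,3,-42
SSC,ssc2.1,2,46-63,0-36,2,10
SSC,ssc2.2,2,86-139,42-49,2,14
SSC,ssc3.1,3,11-124,58-62,3,14
SSC,ssc4.1,4,41-94,4-57,2,-13
SSC,ssc5.1,5,4-32,0-0.5,2,-8
SSC,ssc9.1,9,13-92,4-57,2,9
TA,ta2.1,2,46-63,36-42,2,-16
EC,ec_a2.1,2,1-46,28-35,2,-15
EC,ec_a7.1,7,77-100,60-63,2,-20
IC,ic_L2.1,2,63-86,42-50,2,-11
IC,ic_L5.1,5,4-84,0-0.5,2,8
IC,ic_a10.1,10,27-31,0-2.8,2,18
IC,ic_H1.1,1,50-135,5-78,2,2
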