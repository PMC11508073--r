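condition,arrest_agent,culture_hours,dose_gy,cells_scored,dicentrics
calyculinA_36h,calyculin_A,36,0,102,0
calyculinA_36h,calyculin_A,36,1,50,10
calyculinA_36h,calyculin_A,36,2,50,22
calyculinA_36h,calyculin_A,36,4,20,31
calyculinA_48h,calyculin_A,48,0,50,1
calyculinA_48h,calyculin_A,48,1,50,9
calyculinA_48h,calyculin_A,48,2,50,30
calyculinA_48h,calyculin_A,48,4,17,31
colcemid_48h,colcemid,48,0,500,0
colcemid_48h,colcemid,48,1,100,20
colcemid_48h,colcemid,48,2,100,42
colcemid_48h,colcemid,48,4,100,185
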