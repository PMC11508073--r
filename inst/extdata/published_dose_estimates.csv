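condition,culture_hours,delivered_label_gy,exposure_gy,estimate_gy,lcl_gy,ucl_gy
calyculinA_36h,36,0,0,0,0,0
calyculinA_36h,36,1,1,1.02,0.60,1.53
calyculinA_36h,36,2,2,1.71,1.27,2.20
calyculinA_36h,36,3,4,3.58,2.87,4.35
calyculinA_48h,48,0,0,0.11,0,0.11
calyculinA_48h,48,1,1,0.95,0.53,1.46
calyculinA_48h,48,2,2,2.07,1.62,2.55
calyculinA_48h,48,3,4,3.92,3.15,4.76
colcemid_48h,48,0,0,0,0,0
colcemid_48h,48,1,1,1.02,0.72,1.37
colcemid_48h,48,2,2,1.66,1.35,2.00
colcemid_48h,48,3,4,3.95,3.64,4.28
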