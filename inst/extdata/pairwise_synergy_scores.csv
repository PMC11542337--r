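drug_a,class_a,drug_b,class_b,ci,eob_sum,ddss_pct,paper_flag
DEF,mTOR,INK,mTOR,5.33,-0.01,-9.82,
DEF,mTOR,PAC,MT,1.14,-0.24,-0.58,
DEF,mTOR,VIN,MT,1.2,-0.24,-1.61,
DEF,mTOR,AAG,HSP,1.06,0.17,5.76,b
DEF,mTOR,AUY,HSP,2.15,-0.39,-5.83,
DEF,mTOR,PS,PROT,1.18,-0.12,0.86,
DEF,mTOR,MG,PROT,1.49,-0.17,-0.76,
DEF,mTOR,ETO,DNA,9.39,-0.05,-0.57,
DEF,mTOR,GEM,DNA,0.95,-0.42,1.61,c
DEF,mTOR,PAN,HDAC,0.84,0.2,7.07,a
DEF,mTOR,SAHA,HDAC,0.96,-0.04,3.01,c
INK,mTOR,PAC,MT,1.66,-0.12,3.95,
INK,mTOR,VIN,MT,1.34,-0.54,0.87,
INK,mTOR,AAG,HSP,1.03,0.41,14.8,b
INK,mTOR,AUY,HSP,1.47,-0.05,5.91,
INK,mTOR,PS,PROT,2.22,-0.31,-2.99,
INK,mTOR,MG,PROT,3.15,-0.2,-2.5,
INK,mTOR,ETO,DNA,9.25,-0.66,-4.96,
INK,mTOR,GEM,DNA,2.43,-0.49,4.85,
INK,mTOR,PAN,HDAC,0.51,0.67,21.09,a
INK,mTOR,SAHA,HDAC,0.57,0.41,14.08,a
PAC,MT,VIN,MT,0.85,-0.87,2.08,c
PAC,MT,AAG,HSP,1.45,-0.37,2.45,
PAC,MT,AUY,HSP,2.12,-0.65,-6.09,
PAC,MT,PS,PROT,1.16,-0.25,5.71,
PAC,MT,MG,PROT,1.71,-0.26,5.98,
PAC,MT,ETO,DNA,1.53,-1.09,-5.47,
PAC,MT,GEM,DNA,0.98,-0.98,-4.52,
PAC,MT,PAN,HDAC,1.32,-0.17,4.68,
PAC,MT,SAHA,HDAC,1.03,-0.15,2.77,
VIN,MT,AAG,HSP,2.18,-0.48,2.9,
VIN,MT,AUY,HSP,2.41,-0.64,-3.76,
VIN,MT,PS,PROT,1.67,-0.41,4.94,
VIN,MT,MG,PROT,3.52,-0.57,1.72,
VIN,MT,ETO,DNA,1.71,-1.34,-2.53,
VIN,MT,GEM,DNA,0.66,-1.18,-5.76,
VIN,MT,PAN,HDAC,1.25,-0.11,10.18,
VIN,MT,SAHA,HDAC,1.08,-0.16,4.64,
AAG,HSP,AUY,HSP,1.59,-0.75,2.41,
AAG,HSP,PS,PROT,1.85,-0.69,0.43,
AAG,HSP,MG,PROT,3.06,-0.86,-0.31,
AAG,HSP,ETO,DNA,2.91,-0.51,7.28,
AAG,HSP,GEM,DNA,3.09,-0.58,5.92,
AAG,HSP,PAN,HDAC,1.96,-0.59,4.44,
AAG,HSP,SAHA,HDAC,2.13,-0.3,1.88,
AUY,HSP,PS,PROT,4.59,-1.26,-7.06,
AUY,HSP,MG,PROT,3.34,-1.06,-1.59,
AUY,HSP,ETO,DNA,1.5,-0.46,11.43,
AUY,HSP,GEM,DNA,2.64,-0.91,0.79,
AUY,HSP,PAN,HDAC,2.92,-0.95,2.58,
AUY,HSP,SAHA,HDAC,2.45,-0.43,2.61,
PS,PROT,MG,PROT,1.69,-0.81,-3.68,
PS,PROT,ETO,DNA,3.72,-0.81,-1.82,
PS,PROT,GEM,DNA,5.86,-0.9,0.54,
PS,PROT,PAN,HDAC,2.1,-0.43,5.03,
PS,PROT,SAHA,HDAC,1.16,0.11,9.11,b
MG,PROT,ETO,DNA,4.92,-0.68,2.13,
MG,PROT,GEM,DNA,6.48,-0.75,-0.9,
MG,PROT,PAN,HDAC,1.81,-0.54,3.92,
MG,PROT,SAHA,HDAC,1.16,-0.05,5.67,
ETO,DNA,GEM,DNA,4.4,-1.14,-3.66,
ETO,DNA,PAN,HDAC,1.99,-0.49,8.33,
ETO,DNA,SAHA,HDAC,3.44,-0.15,2.89,
GEM,DNA,PAN,HDAC,4.02,-0.57,3.04,
GEM,DNA,SAHA,HDAC,6.48,-0.3,-1.14,
PAN,HDAC,SAHA,HDAC,1.7,-0.47,-0.93,
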