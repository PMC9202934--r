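medium,source,item,metal,mean,sd,unit
water,IWW,-,Fe,6.72,0.023,mg/l
water,IWW,-,Pb,0.393,0.13,mg/l
water,IWW,-,Cr,0.537,0.01,mg/l
water,IWW,-,Ni,0.121,0.01,mg/l
water,IWW,-,Mn,0.125,0.02,mg/l
water,IWW,-,Co,0.204,0.03,mg/l
water,TWW,-,Fe,1.17,0.078,mg/l
water,TWW,-,Pb,0.043,0.014,mg/l
water,TWW,-,Cr,0.416,0.05,mg/l
water,TWW,-,Ni,0.091,0.01,mg/l
water,TWW,-,Mn,0.033,0.01,mg/l
water,TWW,-,Co,0.116,0.02,mg/l
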