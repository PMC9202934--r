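medium,source,item,metal,mean,sd,unit
soil,IWW,-,Fe,47.27,0.12,mg/kg dw
soil,IWW,-,Pb,2.92,0.10,mg/kg dw
soil,IWW,-,Cr,2.90,0.04,mg/kg dw
soil,IWW,-,Ni,1.02,0.02,mg/kg dw
soil,IWW,-,Mn,0.90,0.03,mg/kg dw
soil,IWW,-,Co,0.68,0.05,mg/kg dw
soil,TWW,-,Fe,17.12,0.27,mg/kg dw
soil,TWW,-,Pb,2.12,0.21,mg/kg dw
soil,TWW,-,Cr,2.03,0.03,mg/kg dw
soil,TWW,-,Ni,0.76,0.04,mg/kg dw
soil,TWW,-,Mn,0.23,0.01,mg/kg dw
soil,TWW,-,Co,0.49,0.01,mg/kg dw
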