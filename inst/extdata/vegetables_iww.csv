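medium,source,item,metal,mean,sd,unit
vegetable,IWW,Ladyfinger,Fe,8.09,0.06,mg/kg dw
vegetable,IWW,Ladyfinger,Pb,3.51,0.27,mg/kg dw
vegetable,IWW,Ladyfinger,Cr,0.43,0.04,mg/kg dw
vegetable,IWW,Ladyfinger,Ni,0.22,0.05,mg/kg dw
vegetable,IWW,Ladyfinger,Mn,0.21,0.01,mg/kg dw
vegetable,IWW,Ladyfinger,Co,0.09,0.05,mg/kg dw
vegetable,IWW,Pumpkin,Fe,24.90,0.18,mg/kg dw
vegetable,IWW,Pumpkin,Pb,1.61,0.21,mg/kg dw
vegetable,IWW,Pumpkin,Cr,0.51,0.03,mg/kg dw
vegetable,IWW,Pumpkin,Ni,0.39,0.04,mg/kg dw
vegetable,IWW,Pumpkin,Mn,0.97,0.01,mg/kg dw
vegetable,IWW,Pumpkin,Co,0.07,0.01,mg/kg dw
vegetable,IWW,Onion,Fe,3.60,0.04,mg/kg dw
vegetable,IWW,Onion,Pb,0.67,0.03,mg/kg dw
vegetable,IWW,Onion,Cr,0.44,0.06,mg/kg dw
vegetable,IWW,Onion,Ni,0.25,0.04,mg/kg dw
vegetable,IWW,Onion,Mn,0.16,0.02,mg/kg dw
vegetable,IWW,Onion,Co,0.14,0.06,mg/kg dw
vegetable,IWW,Green pepper,Fe,1.70,0.04,mg/kg dw
vegetable,IWW,Green pepper,Pb,3.58,0.16,mg/kg dw
vegetable,IWW,Green pepper,Cr,2.30,0.06,mg/kg dw
vegetable,IWW,Green pepper,Ni,0.20,0.06,mg/kg dw
vegetable,IWW,Green pepper,Mn,0.08,0.03,mg/kg dw
vegetable,IWW,Green pepper,Co,0.10,0.01,mg/kg dw
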