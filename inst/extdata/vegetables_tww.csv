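medium,source,item,metal,mean,sd,unit
vegetable,TWW,Ladyfinger,Fe,2.22,0.10,mg/kg dw
vegetable,TWW,Ladyfinger,Pb,0.73,0.11,mg/kg dw
vegetable,TWW,Ladyfinger,Cr,0.39,0.04,mg/kg dw
vegetable,TWW,Ladyfinger,Ni,0.18,0.18,mg/kg dw
vegetable,TWW,Ladyfinger,Mn,0.16,0.02,mg/kg dw
vegetable,TWW,Ladyfinger,Co,0.04,0.02,mg/kg dw
vegetable,TWW,Pumpkin,Fe,3.13,0.18,mg/kg dw
vegetable,TWW,Pumpkin,Pb,0.91,0.06,mg/kg dw
vegetable,TWW,Pumpkin,Cr,0.53,0.10,mg/kg dw
vegetable,TWW,Pumpkin,Ni,0.27,0.04,mg/kg dw
vegetable,TWW,Pumpkin,Mn,0.42,0.04,mg/kg dw
vegetable,TWW,Pumpkin,Co,0.01,0.02,mg/kg dw
vegetable,TWW,Onion,Fe,2.16,0.11,mg/kg dw
vegetable,TWW,Onion,Pb,0.74,0.04,mg/kg dw
vegetable,TWW,Onion,Cr,0.45,0.06,mg/kg dw
vegetable,TWW,Onion,Ni,0.24,0.02,mg/kg dw
vegetable,TWW,Onion,Mn,0.28,0.02,mg/kg dw
vegetable,TWW,Onion,Co,0.06,0.05,mg/kg dw
vegetable,TWW,Green pepper,Fe,0.78,0.10,mg/kg dw
vegetable,TWW,Green pepper,Pb,0.69,0.07,mg/kg dw
vegetable,TWW,Green pepper,Cr,0.60,0.04,mg/kg dw
vegetable,TWW,Green pepper,Ni,0.150,0.03,mg/kg dw
vegetable,TWW,Green pepper,Mn,0.08,0.01,mg/kg dw
vegetable,TWW,Green pepper,Co,0.12,0.04,mg/kg dw
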