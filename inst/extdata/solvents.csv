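name,smiles
water,O
ethanol,CCO
methanol,CO
propan-2-ol,CC(C)O
acetone,CC(C)=O
dichloromethane,ClCCl
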