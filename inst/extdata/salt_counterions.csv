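name,smiles,charge
hydrochloride,Cl,0
hydrobromide,Br,0
chloride,[Cl-],-1
bromide,[Br-],-1
sodium,[Na+],1
potassium,[K+],1
calcium,[Ca+2],2
magnesium,[Mg+2],2
mesylate,CS(=O)(=O)O,0
mesylate anion,CS(=O)(=O)[O-],-1
besylate,OS(=O)(=O)c1ccccc1,0
tosylate,Cc1ccc(cc1)S(=O)(=O)O,0
maleate,OC(=O)C=CC(=O)O,0
tartrate,OC(C(O)C(=O)O)C(=O)O,0
succinate,OC(=O)CCC(=O)O,0
phosphate,OP(=O)(O)O,0
sulfate,OS(=O)(=O)O,0
nitrate,[O-][N+](=O)O,0
tromethamine,NC(CO)(CO)CO,0
tromethamine cation,[NH3+]C(CO)(CO)CO,1
ammonium,[NH4+],1
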