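name,smiles,anion_smiles,anion_charge,basic_amine,oversized
aspirin,CC(=O)Oc1ccccc1C(=O)O,CC(=O)Oc1ccccc1C(=O)[O-],1,FALSE,FALSE
paracetamol,CC(=O)Nc1ccc(O)cc1,,0,FALSE,FALSE
ibuprofen,CC(C)Cc1ccc(cc1)C(C)C(=O)O,CC(C)Cc1ccc(cc1)C(C)C(=O)[O-],1,FALSE,FALSE
naproxen,COc1ccc2cc(ccc2c1)C(C)C(=O)O,COc1ccc2cc(ccc2c1)C(C)C(=O)[O-],1,FALSE,FALSE
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,,0,FALSE,FALSE
atenolol,CC(C)NCC(O)COc1ccc(CC(N)=O)cc1,,0,TRUE,FALSE
propranolol,CC(C)NCC(O)COc1cccc2ccccc12,,0,TRUE,FALSE
metformin,CN(C)C(=N)NC(=N)N,,0,TRUE,FALSE
diazepam,CN1C(=O)CN=C(c2ccccc2)c2cc(Cl)ccc21,,0,FALSE,FALSE
warfarin,CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O,,0,FALSE,FALSE
furosemide,NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl,NS(=O)(=O)c1cc(C(=O)[O-])c(NCc2ccco2)cc1Cl,1,FALSE,FALSE
sulfamethoxazole,Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1,,0,FALSE,FALSE
ciprofloxacin,O=C(O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O,[O-]C(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O,1,TRUE,FALSE
lidocaine,CCN(CC)CC(=O)Nc1c(C)cccc1C,,0,TRUE,FALSE
phenytoin,O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1,,0,FALSE,FALSE
chlorpromazine,CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21,,0,TRUE,FALSE
fluoxetine,CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1,,0,TRUE,FALSE
sertraline,CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc12,,0,TRUE,FALSE
metoprolol,COCCc1ccc(OCC(O)CNC(C)C)cc1,,0,TRUE,FALSE
ranitidine,CNC(=C[N+](=O)[O-])NCCSCc1ccc(CN(C)C)o1,,0,TRUE,FALSE
cimetidine,Cc1nc[nH]c1CSCCNC(=NC)NC#N,,0,FALSE,FALSE
allopurinol,O=c1[nH]cnc2[nH]ncc12,,0,FALSE,FALSE
theophylline,Cn1c(=O)c2[nH]cnc2n(C)c1=O,,0,FALSE,FALSE
salbutamol,CC(C)(C)NCC(O)c1ccc(O)c(CO)c1,,0,TRUE,FALSE
gabapentin,NCC1(CC(=O)O)CCCCC1,,0,FALSE,FALSE
tramadol,CN(C)CC1CCCCC1(O)c1cccc(OC)c1,,0,TRUE,FALSE
celecoxib,Cc1ccc(cc1)-c1cc(nn1-c1ccc(cc1)S(N)(=O)=O)C(F)(F)F,,0,FALSE,FALSE
carbamazepine,NC(=O)N1c2ccccc2C=Cc2ccccc21,,0,FALSE,FALSE
loratadine,CCOC(=O)N1CCC(=C2c3ccc(Cl)cc3CCc3cccnc32)CC1,,0,FALSE,FALSE
losartan,CCCCc1nc(Cl)c(CO)n1Cc1ccc(-c2ccccc2-c2nnn[nH]2)cc1,,0,FALSE,FALSE
amlodipine,CCOC(=O)C1=C(COCCN)NC(C)=C(C(=O)OC)C1c1ccccc1Cl,,0,TRUE,FALSE
valsartan,CCCCC(=O)N(Cc1ccc(-c2ccccc2-c2nnn[nH]2)cc1)C(C(C)C)C(=O)O,,0,FALSE,FALSE
pemetrexed,Nc1nc2[nH]cc(CCc3ccc(C(=O)NC(CCC(=O)O)C(=O)O)cc3)c2c(=O)[nH]1,Nc1nc2[nH]cc(CCc3ccc(C(=O)NC(CCC(=O)[O-])C(=O)[O-])cc3)c2c(=O)[nH]1,2,FALSE,FALSE
omeprazole,COc1ccc2[nH]c(S(=O)Cc3ncc(C)c(OC)c3C)nc2c1,,0,FALSE,FALSE
fluconazole,OC(Cn1cncn1)(Cn1cncn1)c1ccc(F)cc1F,,0,FALSE,FALSE
bulkavirin,CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC,,0,FALSE,TRUE
maxipeptide,CC(N)C(=O)NC(CC(C)C)C(=O)NC(CC(C)C)C(=O)NC(CC(C)C)C(=O)NC(CC(C)C)C(=O)NC(CC(C)C)C(=O)NC(Cc1ccccc1)C(=O)NC(Cc1ccccc1)C(=O)NC(Cc1ccccc1)C(=O)NC(Cc1ccccc1)C(=O)O,,0,FALSE,TRUE
gigalidone,CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC(=O)OCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC,,0,FALSE,TRUE
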