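smiles,reference_scaffold
Cc1ccccc1,c1ccccc1
CCc1ccc(O)cc1,c1ccccc1
Clc1ccccc1Br,c1ccccc1
Cc1ccncc1,c1ccncc1
COc1ccc2[nH]ccc2c1,c1ccc2[nH]ccc2c1
CC(=O)Nc1ccc(-c2ccccc2)cc1,c1ccc(-c2ccccc2)cc1
CCN(CC)c1ccc2ncccc2c1,c1ccc2ncccc2c1
Cc1ccc2ccccc2c1,c1ccc2ccccc2c1
O=C(Nc1ccc(F)cc1)c1ccccc1,O=C(Nc1ccccc1)c1ccccc1
O=C(/C=C/c1ccc(O)cc1)c1ccccc1,O=C(/C=C/c1ccccc1)c1ccccc1
CC(=O)Oc1ccccc1C(=O)O,c1ccccc1
CC(C)Cc1ccc(C(C)C(=O)O)cc1,c1ccccc1
CN1CCC[C@H]1c1cccnc1,c1cncc([C@@H]2CCCN2)c1
Cn1cnc2c1c(=O)n(C)c(=O)n2C,O=c1[nH]c(=O)c2[nH]cnc2[nH]1
NC(=O)c1ccc(O)cc1,c1ccccc1
Oc1ccc(CCN)cc1,c1ccccc1
COc1cc2c(cc1OC)CCN2,c1ccc2c(c1)CCN2
O=C1CCCCC1,O=C1CCCCC1
C=C1CCCCC1,C=C1CCCCC1
O=C1CCCN1C,O=C1CCCN1
c1ccc(N2CCNCC2)cc1,c1ccc(N2CCNCC2)cc1
O=S(=O)(N)c1ccc(Cl)cc1,c1ccccc1
N#Cc1ccc(O)cc1,c1ccccc1
CC(N)Cc1ccccc1,c1ccccc1
OCC1OC(O)C(O)C(O)C1O,C1CCOCC1
C1CCC2CCCCC2C1,C1CCC2CCCCC2C1
C1CC1CC2CC2,C1CC1CC1CC1
O=C(CCc1ccccc1)c1ccccc1,O=C(CCc1ccccc1)c1ccccc1
CC12CCC(CC1)C(C)(C)O2,C1CC2CCC1CO2
c1ccc(Cc2ccccc2)cc1,c1ccc(Cc2ccccc2)cc1
c1ccc(COc2ccccc2)cc1,c1ccc(COc2ccccc2)cc1
c1ccc(-c2ccc(-c3ccccc3)cc2)cc1,c1ccc(-c2ccc(-c3ccccc3)cc2)cc1
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1,c1ccccc1
CN1C2CCC1CC(OC(=O)C(CO)c1ccccc1)C2,O=C(Cc1ccccc1)OC1CC2CCC(C1)N2
NCCc1c[nH]c2ccccc12,c1ccc2[nH]ccc2c1
Oc1ccc2c(c1)OC(c1ccccc1)CC2,c1ccc(C2CCc3ccccc3O2)cc1
O=c1ccc2ccccc2o1,O=c1ccc2ccccc2o1
O=c1cc(-c2ccccc2)oc2ccccc12,O=c1cc(-c2ccccc2)oc2ccccc12
CC(=O)c1ccc2ccccc2c1,c1ccc2ccccc2c1
O=C(O)CCCCC1CCSS1,C1CSSC1
NC1CCCCC1N,C1CCCCC1
O=C1NC(=O)c2ccccc21,O=C1NC(=O)c2ccccc21
CC1=CC(=O)CC(C)(C)C1,O=C1C=CCCC1
c1cnc2[nH]ccc2c1,c1cnc2[nH]ccc2c1
CC(C)c1ccc(C)cc1O,c1ccccc1
CCOC(=O)c1cncn1C,c1c[nH]cn1
O=C(c1ccccc1)c1ccccc1,O=C(c1ccccc1)c1ccccc1
CN(C)CCCN1c2ccccc2CCc2ccccc21,c1ccc2c(c1)CCc1ccccc1N2
CCCCC,
CC(C)CC(N)C(=O)O,
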