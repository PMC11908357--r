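CC(=O)Oc1ccccc1C(=O)[O-]
Cn1cnc2c1c(=O)n(C)c(=O)n2C
CC(C)Cc1ccc(cc1)C(C)C(=O)[O-]
CC(=O)Nc1ccc(O)cc1
COc1ccc2cc(ccc2c1)C(C)C(=O)[O-]
CN1CCCC1c1cccnc1
NC(=N)c1ccccc1
c1ccc2ncccc2c1
c1ccc2[nH]ccc2c1
Cc1cnc[nH]1
OCC1OC(O)C(O)C(O)C1O
NC(Cc1ccccc1)C(=O)O
Oc1ccccc1C(=O)O
CCOC(=O)c1ccc(N)cc1
CCN(CC)CCOC(=O)c1ccc(N)cc1
Nc1ccc(cc1)S(N)(=O)=O
Cc1ccccc1
OC(=O)c1ccco1
NC(=O)c1cccs1
N#Cc1cccnc1
COc1ccccc1
c1ccc2ccccc2c1
OC1CCCCC1
C1CNCCN1
C1COCCN1
c1ccc2occc2c1
c1ccc2sccc2c1
Oc1ccccc1O
Oc1cccc(O)c1
Nc1ccc(Cl)cc1
Cc1ccc(Br)cc1
Ic1ccccc1
FC(F)(F)c1ccccc1
CC(=O)c1ccccc1
O=Cc1ccccc1
C=Cc1ccccc1
C#Cc1ccccc1
OC(=O)C=Cc1ccccc1
O=C1C=Cc2ccccc2O1
O=C1C=CNC(=O)N1
Nc1ncnc2[nH]cnc12
NCCc1c[nH]cn1
NCCc1c[nH]c2ccccc12
NCCc1ccc(O)c(O)c1
NCCc1ccc(O)cc1
CC(N)Cc1ccccc1
COC(=O)c1ccccc1
CCOC(=O)C
CCOCC
Cc1cc(C)cc(C)c1
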