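ethanol	CCO
aspirin	CC(=O)OC1=CC=CC=C1C(=O)O
paracetamol	CC(=O)NC1=CC=C(O)C=C1
caffeine	CN1C=NC2=C1C(=O)N(C)C(=O)N2C
ibuprofen	CC(C)CC1=CC=C(C=C1)C(C)C(=O)O
chlorobenzene	ClC1=CC=CC=C1
phenol	OC1=CC=CC=C1
naphthalene	C1=CC=C2C=CC=CC2=C1
tosylamide	CC1=CC=C(C=C1)S(=O)(=O)N
mol10	COC1=CC2=C(C=C1)C=C(C2)CC(=O)O
dmtryptamine	CN(C)CCC1=CNC2=CC=CC=C12
benzocaine	NC1=CC=C(C=C1)C(=O)OCC
salicylic	OC(=O)C1=CC=CC=C1O
amphetamine	CC(N)CC1=CC=CC=C1
mol15	CN1CCC23C4OC(=O)C2=CC(=O)CCC3N(C)CC14
lipoic	O=C(O)CCCCC1CCSS1
tryptophan	NC(CC1=CNC2=CC=CC=C12)C(=O)O
atenolol	CC(C)NCC(O)COC1=CC=C(CC(N)=O)C=C1
nicotine	CN1CCCC1C2=CN=CC=C2
glucose	OCC1OC(O)C(O)C(O)C1O
serotonin	NCCC1=CNC2=CC=C(O)C=C12
captopril	CC(CS)C(=O)N1CCCC1C(=O)O
terbutaline	CC(C)(C)NCC(O)C1=CC(O)=CC(O)=C1
ddt	ClC1=CC=C(C=C1)C(C1=CC=C(Cl)C=C1)C(Cl)(Cl)Cl
homoveratrylamine	COC1=CC=C(CCN)C=C1OC
mol26	CN1CCN(CC1)C1=NC2=CC=CC=C2NC1=O
niacin	OC(=O)C1=CN=CC=C1
adenine	NC1=NC=NC2=C1N=CN2
barbituric	O=C1NC(=O)NC(=O)C1
thymidine	CC1=CN(C2CC(O)C(CO)O2)C(=O)NC1=O
mol31	CC(C)C1=NC(=CS1)CN(C)C(=O)NC(C(C)C)C(=O)O
metformin	CN(C)C(=N)NC(=N)N
lysine	NCCCCC(N)C(=O)O
citric	OC(=O)CC(O)(CC(=O)O)C(=O)O
penicillinG	CC1(C)SC2C(NC(=O)CC3=CC=CC=C3)C(=O)N2C1C(=O)O
cephalothinish	CC(=O)OCC1=C(N2C(SC1)C(NC(=O)CC1=CC=CC=C1)C2=O)C(=O)O
mol37	CN1C2=C(C=CC=C2)C(=O)N(C)C1=O
daunomycinone	COC1=CC=CC2=C1C(=O)C1=C(O)C3=C(CC(O)(CC3O)C(C)=O)C(O)=C1C2=O
mol39	CC(C)(C)OC(=O)NC(CC1=CC=CC=C1)C(O)CN
mol40	CC1=C(C=C(C=C1)S(=O)(=O)NC(=O)NN1CC2CCCC2C1)Cl
mol41	COC1=C(OC)C=C2C(=O)C(CC3=CC=C(OC)C(OC)=C3)COC2=C1
mol42	CC(C)CC(NC(=O)C(CC1=CC=CC=C1)NC(=O)OC(C)(C)C)C(=O)O
mol43	CN1CCC(CC1)=C1C2=CC=CC=C2CCC2=CC=CC=C12
mol44	ClC1=CC2=C(C=C1)N(C1CCN(CCCN3C=NC=N3)CC1)C(=O)N2
mol45	CC1=CC(C)=C(NC(=O)CN(CC(=O)O)CC(=O)O)C(C)=C1Br
mol46	OC(CNC(C)(C)C)COC1=CC=CC2=C1CC(O)C2O
acetazolamide	CC(=O)NC1=NN=C(S1)S(N)(=O)=O
haloperidol	FC1=CC=C(C=C1)C(=O)CCCN1CCC(O)(CC1)C1=CC=C(Cl)C=C1
mol49	COC1=CC=C(C=C1)CCNC(C)=O
mol50	CC(C)(C)C1=CC(=C(O)C(=C1)C(C)(C)C)CC1=CC=CC=C1
mol51	NS(=O)(=O)C1=CC2=C(NC(NS2(=O)=O)C2CCCCC2)C=C1Cl
procainamide	CCN(CC)CCNC(=O)C1=CC=C(N)C=C1
mol53	CC(O)C1=CC=C(C=C1)CC(C)N
phenolphthalein	OC1=CC=C(C=C1)C1(OC(=O)C2=CC=CC=C12)C1=CC=C(O)C=C1
meperidine	CCOC(=O)C1(CCN(C)CC1)C1=CC=CC=C1
cluster01	CN1C=NC2=C1C(=O)N(C)C(=O)N2C.COC1=CC=C(C=C1)CCNC(C)=O.CC1=C(C=C(C=C1)S(=O)(=O)NC(=O)NN1CC2CCCC2C1)Cl.NC(CC1=CNC2=CC=CC=C12)C(=O)O.CN1CCN(CC1)C1=NC2=CC=CC=C2NC1=O.NS(=O)(=O)C1=CC2=C(NC(NS2(=O)=O)C2CCCCC2)C=C1Cl.CC(=O)NC1=NN=C(S1)S(N)(=O)=O.CC(=O)OCC1=C(N2C(SC1)C(NC(=O)CC1=CC=CC=C1)C2=O)C(=O)O
cluster02	CN(C)CCC1=CNC2=CC=CC=C12.CC1(C)SC2C(NC(=O)CC3=CC=CC=C3)C(=O)N2C1C(=O)O.OC(=O)CC(O)(CC(=O)O)C(=O)O.OC1=CC=C(C=C1)C1(OC(=O)C2=CC=CC=C12)C1=CC=C(O)C=C1.CCN(CC)CCNC(=O)C1=CC=C(N)C=C1.CC(=O)OCC1=C(N2C(SC1)C(NC(=O)CC1=CC=CC=C1)C2=O)C(=O)O.NC(CC1=CNC2=CC=CC=C12)C(=O)O.FC1=CC=C(C=C1)C(=O)CCCN1CCC(O)(CC1)C1=CC=C(Cl)C=C1
cluster03	COC1=CC=C(CCN)C=C1OC.CC1=CC(C)=C(NC(=O)CN(CC(=O)O)CC(=O)O)C(C)=C1Br.ClC1=CC=C(C=C1)C(C1=CC=C(Cl)C=C1)C(Cl)(Cl)Cl.CN1C2=C(C=CC=C2)C(=O)N(C)C1=O.CC1=CC(C)=C(NC(=O)CN(CC(=O)O)CC(=O)O)C(C)=C1Br.ClC1=CC2=C(C=C1)N(C1CCN(CCCN3C=NC=N3)CC1)C(=O)N2.CN1CCC(CC1)=C1C2=CC=CC=C2CCC2=CC=CC=C12.NS(=O)(=O)C1=CC2=C(NC(NS2(=O)=O)C2CCCCC2)C=C1Cl
cluster04	CCOC(=O)C1(CCN(C)CC1)C1=CC=CC=C1.CC(C)(C)OC(=O)NC(CC1=CC=CC=C1)C(O)CN.FC1=CC=C(C=C1)C(=O)CCCN1CCC(O)(CC1)C1=CC=C(Cl)C=C1.CC1=C(C=C(C=C1)S(=O)(=O)NC(=O)NN1CC2CCCC2C1)Cl.CC(C)CC1=CC=C(C=C1)C(C)C(=O)O.CC(O)C1=CC=C(C=C1)CC(C)N.NCCC1=CNC2=CC=C(O)C=C12
cluster05	OC(=O)CC(O)(CC(=O)O)C(=O)O.CC1(C)SC2C(NC(=O)CC3=CC=CC=C3)C(=O)N2C1C(=O)O.FC1=CC=C(C=C1)C(=O)CCCN1CCC(O)(CC1)C1=CC=C(Cl)C=C1.CC(C)NCC(O)COC1=CC=C(CC(N)=O)C=C1.CC(=O)OCC1=C(N2C(SC1)C(NC(=O)CC1=CC=CC=C1)C2=O)C(=O)O.CC(C)CC(NC(=O)C(CC1=CC=CC=C1)NC(=O)OC(C)(C)C)C(=O)O
cluster06	CC(C)(C)OC(=O)NC(CC1=CC=CC=C1)C(O)CN.ClC1=CC=C(C=C1)C(C1=CC=C(Cl)C=C1)C(Cl)(Cl)Cl.FC1=CC=C(C=C1)C(=O)CCCN1CCC(O)(CC1)C1=CC=C(Cl)C=C1.CC1=CC(C)=C(NC(=O)CN(CC(=O)O)CC(=O)O)C(C)=C1Br.CN1CCC23C4OC(=O)C2=CC(=O)CCC3N(C)CC14.CN1C=NC2=C1C(=O)N(C)C(=O)N2C.CC1(C)SC2C(NC(=O)CC3=CC=CC=C3)C(=O)N2C1C(=O)O
cluster07	CC(C)C1=NC(=CS1)CN(C)C(=O)NC(C(C)C)C(=O)O.CC(C)NCC(O)COC1=CC=C(CC(N)=O)C=C1.CC1(C)SC2C(NC(=O)CC3=CC=CC=C3)C(=O)N2C1C(=O)O.CC1=C(C=C(C=C1)S(=O)(=O)NC(=O)NN1CC2CCCC2C1)Cl.CN1CCC23C4OC(=O)C2=CC(=O)CCC3N(C)CC14.CC(C)NCC(O)COC1=CC=C(CC(N)=O)C=C1.CC(CS)C(=O)N1CCCC1C(=O)O
cluster08	CC(C)NCC(O)COC1=CC=C(CC(N)=O)C=C1.NC(CC1=CNC2=CC=CC=C12)C(=O)O.CN1C2=C(C=CC=C2)C(=O)N(C)C1=O.CC1=CC(C)=C(NC(=O)CN(CC(=O)O)CC(=O)O)C(C)=C1Br.COC1=CC=C(CCN)C=C1OC.CN1CCC(CC1)=C1C2=CC=CC=C2CCC2=CC=CC=C12.COC1=CC=C(CCN)C=C1OC.NC(CC1=CNC2=CC=CC=C12)C(=O)O
cluster09	OC(=O)CC(O)(CC(=O)O)C(=O)O.COC1=CC=C(C=C1)CCNC(C)=O.ClC1=CC=C(C=C1)C(C1=CC=C(Cl)C=C1)C(Cl)(Cl)Cl.CN1CCN(CC1)C1=NC2=CC=CC=C2NC1=O.CN1C=NC2=C1C(=O)N(C)C(=O)N2C.CCOC(=O)C1(CCN(C)CC1)C1=CC=CC=C1.CC(CS)C(=O)N1CCCC1C(=O)O
cluster10	CC(C)C1=NC(=CS1)CN(C)C(=O)NC(C(C)C)C(=O)O.CC(C)C1=NC(=CS1)CN(C)C(=O)NC(C(C)C)C(=O)O.COC1=CC2=C(C=C1)C=C(C2)CC(=O)O.CN1C2=C(C=CC=C2)C(=O)N(C)C1=O.CC(=O)NC1=NN=C(S1)S(N)(=O)=O.CN1C=NC2=C1C(=O)N(C)C(=O)N2C.CC(C)(C)OC(=O)NC(CC1=CC=CC=C1)C(O)CN
cluster11	COC1=CC=C(CCN)C=C1OC.CC(C)(C)OC(=O)NC(CC1=CC=CC=C1)C(O)CN.CC1=C(C=C(C=C1)S(=O)(=O)NC(=O)NN1CC2CCCC2C1)Cl.CC(=O)NC1=NN=C(S1)S(N)(=O)=O.CCN(CC)CCNC(=O)C1=CC=C(N)C=C1.CC(C)CC(NC(=O)C(CC1=CC=CC=C1)NC(=O)OC(C)(C)C)C(=O)O.COC1=CC=C(CCN)C=C1OC.CN1C=NC2=C1C(=O)N(C)C(=O)N2C.CC(C)(C)NCC(O)C1=CC(O)=CC(O)=C1
cluster12	CN1C=NC2=C1C(=O)N(C)C(=O)N2C.CC(C)NCC(O)COC1=CC=C(CC(N)=O)C=C1.CC(C)C1=NC(=CS1)CN(C)C(=O)NC(C(C)C)C(=O)O.NC(CC1=CNC2=CC=CC=C12)C(=O)O.COC1=CC2=C(C=C1)C=C(C2)CC(=O)O.CCOC(=O)C1(CCN(C)CC1)C1=CC=CC=C1.COC1=C(OC)C=C2C(=O)C(CC3=CC=C(OC)C(OC)=C3)COC2=C1.CN1CCN(CC1)C1=NC2=CC=CC=C2NC1=O.CCN(CC)CCNC(=O)C1=CC=C(N)C=C1
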