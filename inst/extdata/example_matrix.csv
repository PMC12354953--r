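"smiles","task_01","task_02","task_03"
"O(N(F)N(OOC)C)Cl",0,0,1
"ClN(C1(ON1)SO)NBr",1,1,
"ClOC1(P(SF)CO1)P=N",0,0,0
"ClC(OCl)(NN(C)CC)N",0,1,
"O(N(C(CC=C)Br)C=C=O)C",0,0,0
"O(SN)C(P)(ON)S",0,0,0
"C(OP(F)Br)(N(F)O)(Cl)F",1,1,0
"P1(P(Cl)ON=C1)C(F)O",0,0,0
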