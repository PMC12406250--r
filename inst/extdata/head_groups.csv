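group,smiles,group valence,valence first connection atom,second connection atom index,valence second connection atom,maximum number of groups,smiles verbatim
dummy,*,1,1,0,0,1,*
sulfate,OS(=O)(=O)[O-],1,1,0,0,1,OS(O)(O)[O-]
sulfinate,[O-]S=O,1,0,2,1,1,OS(O)[O-]
ketone,C=O,2,2,0,0,1,CO
ester,C(=O)O,2,1,final,1,1,C(O)O
N-N-dimethylaminomethylene,CN(C)C,1,1,0,0,1,CN(C)C
glycoside,C(C1C(C(C(C(O1)O)O)O)O)O,1,1,0,0,1,C([C@@H]1[C@H]([C@@H]([C@H](C(O1)O)O)O)O)O
methylidene,C,2,2,0,0,2,C
methyl,C,1,1,0,0,1,C
methyllidyne,C,3,3,0,0,1,C
amide,C(=O)N,2,1,final,1,1,C(O)N
dimethylammonium oxide,[N+](C)(C)[O-],1,1,0,0,1,[N+](C)(C)[O-]
ethoxy,CCO,2,1,final,1,1,CCO
hydroxyl,O,1,1,0,0,1,O
phosphate,OP(=O)(O)O,1,1,0,0,1,OP(O)(O)O
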