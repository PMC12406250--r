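group,smiles,group valence,valence first connection atom,second connection atom index,valence second connection atom,maximum number of groups,smiles verbatim
dummy,*,1,1,0,0,1,*
methylidene,C,2,1,final,1,1,C
methyl,C,1,1,0,0,3,C
methyllidyne,C,3,3,0,0,3,C
vinylene,C=C,2,1,final,1,1,CC
alkylene,C#C,2,1,final,1,1,C#C
hexylene,CCCCCC,2,1,final,1,1,CCCCCC
disubstituted phenyl,c1ccccc1,2,1,4,1,1,C1CCCCC1
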