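code,name,smiles
A,alanine,[*:1]N[CH](C)C(=O)[*:2]
R,arginine,[*:1]N[CH](CCCNC(=N)N)C(=O)[*:2]
N,asparagine,[*:1]N[CH](CC(=O)N)C(=O)[*:2]
D,aspartate,[*:1]N[CH](CC(=O)O)C(=O)[*:2]
C,cysteine,[*:1]N[CH](CS)C(=O)[*:2]
E,glutamate,[*:1]N[CH](CCC(=O)O)C(=O)[*:2]
Q,glutamine,[*:1]N[CH](CCC(=O)N)C(=O)[*:2]
G,glycine,[*:1]NCC(=O)[*:2]
H,histidine,[*:1]N[CH](Cc1c[nH]cn1)C(=O)[*:2]
I,isoleucine,[*:1]N[CH](C(C)CC)C(=O)[*:2]
L,leucine,[*:1]N[CH](CC(C)C)C(=O)[*:2]
K,lysine,[*:1]N[CH](CCCCN)C(=O)[*:2]
M,methionine,[*:1]N[CH](CCSC)C(=O)[*:2]
F,phenylalanine,[*:1]N[CH](Cc1ccccc1)C(=O)[*:2]
P,proline,[*:1]N1CCCC1C(=O)[*:2]
S,serine,[*:1]N[CH](CO)C(=O)[*:2]
T,threonine,[*:1]N[CH](C(C)O)C(=O)[*:2]
W,tryptophan,[*:1]N[CH](Cc1c[nH]c2ccccc12)C(=O)[*:2]
Y,tyrosine,[*:1]N[CH](Cc1ccc(O)cc1)C(=O)[*:2]
V,valine,[*:1]N[CH](C(C)C)C(=O)[*:2]
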