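resname,atom
SER,OG
CYS,SG
THR,OG1|CG2
VAL,CG1|CG2
LEU,CG
ILE,CD1
MET,SD
PRO,CG
PHE,CZ
TYR,OH
TRP,CZ2
HIS,ND1|CD2
LYS,NZ
ARG,CZ
ASP,CG
GLU,CD
ASN,CG
GLN,CD
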