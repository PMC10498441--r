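smiles	class
CC(=O)O	acid
CCC(=O)O	acid
CCCC(=O)O	acid
OC(=O)c1ccccc1	acid
Cc1ccc(cc1)C(=O)O	acid
OC(=O)c1ccncc1	acid
OC(=O)C1CC1	acid
OC(=O)C1CCC1	acid
COc1ccc(cc1)C(=O)O	acid
OC(=O)c1ccco1	acid
OC(=O)c1cccs1	acid
CC(C)C(=O)O	acid
CC(=O)Cl	acid_chloride
CCC(=O)Cl	acid_chloride
O=C(Cl)c1ccccc1	acid_chloride
Cc1ccc(cc1)C(=O)Cl	acid_chloride
CCN	amine_primary
CCCN	amine_primary
CC(C)N	amine_primary
NC1CC1	amine_primary
NC1CCC1	amine_primary
NCc1ccccc1	amine_primary
Nc1ccccc1	amine_primary
Nc1ccc(C)cc1	amine_primary
Nc1ccc(F)cc1	amine_primary
CCCCN	amine_primary
CNC	amine_secondary
CCNC	amine_secondary
C1CCNC1	amine_secondary
C1CCNCC1	amine_secondary
C1COCCN1	amine_secondary
CNCc1ccccc1	amine_secondary
CO	alcohol
CCO	alcohol
CCCO	alcohol
CC(C)O	alcohol
OCC1CC1	alcohol
OCc1ccccc1	alcohol
CCCCO	alcohol
Oc1ccccc1	phenol
Cc1ccc(O)cc1	phenol
Oc1ccc(F)cc1	phenol
COc1ccc(O)cc1	phenol
Oc1ccncc1	phenol
Brc1ccccc1	aryl_bromide
Cc1ccc(Br)cc1	aryl_bromide
Fc1ccc(Br)cc1	aryl_bromide
Brc1ccncc1	aryl_bromide
COc1ccc(Br)cc1	aryl_bromide
CCBr	alkyl_bromide
CCCBr	alkyl_bromide
BrCC1CC1	alkyl_bromide
BrCc1ccccc1	alkyl_bromide
CCCCBr	alkyl_bromide
OB(O)c1ccccc1	boronic_acid
Cc1ccc(cc1)B(O)O	boronic_acid
OB(O)c1ccc(F)cc1	boronic_acid
COc1ccc(cc1)B(O)O	boronic_acid
CC=O	aldehyde
CCC=O	aldehyde
O=Cc1ccccc1	aldehyde
O=CC1CC1	aldehyde
Cc1ccc(C=O)cc1	aldehyde
CC(C)=O	ketone
CCC(C)=O	ketone
O=C1CCCC1	ketone
CC(=O)c1ccccc1	ketone
CCCC(C)=O	ketone
O=C1CCCCC1	ketone
CCC(=O)CC	ketone
CC#N	nitrile
CCC#N	nitrile
N#Cc1ccccc1	nitrile
N#CCc1ccccc1	nitrile
N#CC1CC1	nitrile
C#CC	alkyne
C#CCC	alkyne
C#Cc1ccccc1	alkyne
C#CCO	alkyne
C#CC1CC1	alkyne
Sc1ccccc1	thiol
CCS	thiol
Cc1ccc(S)cc1	thiol
SCc1ccccc1	thiol
O=C=NCC	isocyanate
O=C=Nc1ccccc1	isocyanate
O=C=NC1CC1	isocyanate
O=C=NCc1ccccc1	isocyanate
CS(=O)(=O)Cl	sulfonyl_chloride
O=S(=O)(Cl)c1ccccc1	sulfonyl_chloride
Cc1ccc(cc1)S(=O)(=O)Cl	sulfonyl_chloride
O=[N+]([O-])c1ccccc1	nitroarene
Cc1ccc(cc1)[N+](=O)[O-]	nitroarene
Fc1ccc(cc1)[N+](=O)[O-]	nitroarene
COc1ccc(cc1)[N+](=O)[O-]	nitroarene
O=[N+]([O-])c1ccncc1	nitroarene
C=Cc1ccccc1	alkene
C=CC	alkene
C=CCC	alkene
C=CC1CC1	alkene
COC(C)=O	methyl_ester
CCC(=O)OC	methyl_ester
COC(=O)c1ccccc1	methyl_ester
COC(=O)C1CC1	methyl_ester
COC(=O)c1ccc(C)cc1	methyl_ester
CC(C)O	sec_alcohol
CCC(C)O	sec_alcohol
OC1CCCC1	sec_alcohol
CC(O)c1ccccc1	sec_alcohol
CCC(O)CC	sec_alcohol
C[Mg]Br	grignard_methyl
[C-]#N	cyanide
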