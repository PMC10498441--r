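template_id	reaction_name	smirks	n_reactants
T01	amide coupling (acid + amine)	[C;!$(C(=O)[O,S]);!R:1](=[O:2])[NX3;!$(N=*);!$(N-[O,N]):3]>>[C:1](=[O:2])[OX2H1].[NX3:3]	2
T02	amide formation (acid chloride + amine)	[C;!$(C(=O)[O,S]);!R:1](=[O:2])[NX3;!$(N=*);!$(N-[O,N]):3]>>[C:1](=[O:2])[Cl].[NX3:3]	2
T03	Fischer esterification (acid + alcohol)	[C;!$(C(=O)[N,S]);!R:1](=[O:2])[OX2:3][CX4:4]>>[C:1](=[O:2])[OX2H1].[OX2H1:3][CX4:4]	2
T04	ester formation (acid chloride + alcohol)	[C;!$(C(=O)[N,S]);!R:1](=[O:2])[OX2:3][CX4:4]>>[C:1](=[O:2])[Cl].[OX2H1:3][CX4:4]	2
T05	phenol acylation (acid chloride + phenol)	[C;!$(C(=O)[N,S]);!R:1](=[O:2])[OX2:3][c:4]>>[C:1](=[O:2])[Cl].[OX2H1:3][c:4]	2
T06	N-alkylation (amine + alkyl bromide)	[NX3;!$(N~[!#6;!#1]);!$(N=*);!$(NC=O):1]-!@[CX4;H2:2]>>[NX3:1].[Br][CX4;H2:2]	2
T07	Williamson ether (phenol + alkyl bromide)	[c:1][OX2;!$(OC=O):2]-!@[CX4;H2:3]>>[c:1][OX2H1:2].[Br][CX4;H2:3]	2
T08	thioether formation (thiol + alkyl bromide)	[SX2;!$(S~[!#6;!#1]):1]-!@[CX4;H2:2]>>[SX2H1:1].[Br][CX4;H2:2]	2
T09	reductive amination (amine + aldehyde)	[NX3;!$(N~[!#6;!#1]);!$(N=*);!$(NC=O):1]-!@[CX4;H2;!$(C[O,S]):2][#6:3]>>[NX3:1].[O]=[CX3H1:2][#6:3]	2
T10	Suzuki coupling (boronic acid + aryl bromide)	[c:1]-!@[c:2]>>[c:1][B]([OX2H1])[OX2H1].[Br][c:2]	2
T11	Buchwald-Hartwig amination (aryl bromide + amine)	[c:1]-!@[NX3;!$(N~[!#6;!#1]);!$(N=*);!$(NC=O):2]>>[c:1][Br].[NX3:2]	2
T12	Sonogashira coupling (aryl bromide + terminal alkyne)	[c:1]-!@[C:2]#[C:3][#6:4]>>[c:1][Br].[CX2H1:2]#[C:3][#6:4]	2
T13	Heck reaction (aryl bromide + terminal alkene)	[c:1]-!@[CX3;H1:2]=[CX3;H1:3][#6:4]>>[c:1][Br].[CX3;H2:2]=[CX3;H1:3][#6:4]	2
T14	sulfonamide formation (sulfonyl chloride + amine)	[S:1](=[O:2])(=[O:3])[NX3:4]>>[S:1](=[O:2])(=[O:3])[Cl].[NX3:4]	2
T15	urea formation (isocyanate + amine)	[NX3;H1:1][C:2](=[O:3])[NX3;!$(N(C=O)C=O):4]>>[N:1]=[C:2]=[O:3].[NX3:4]	2
T16	carbamate formation (isocyanate + alcohol)	[NX3;H1:1][C:2](=[O:3])[OX2:4][CX4:5]>>[N:1]=[C:2]=[O:3].[OX2H1:4][CX4:5]	2
T17	nitro reduction (aniline from nitroarene)	[NX3;H2:1][c:2]>>[O-][N+:1](=[O])[c:2]	1
T18	nitrile reduction (primary amine from nitrile)	[NX3;H2:1][CX4;H2:2][#6:3]>>[N:1]#[C:2][#6:3]	1
T19	nitrile hydration (primary amide from nitrile)	[CX3:1](=[OX1])([NX3;H2])[#6:2]>>[C:1](#[N])[#6:2]	1
T20	nitrile hydrolysis (acid from nitrile)	[CX3:1](=[OX1])([OX2H1])[#6:2]>>[C:1](#[N])[#6:2]	1
T21	aldehyde oxidation (acid from aldehyde)	[CX3:1](=[O:2])([OX2H1])[#6:3]>>[CX3H1:1](=[O:2])[#6:3]	1
T22	alcohol oxidation (ketone from secondary alcohol)	[#6:1][CX3:2](=[O:3])[#6:4]>>[#6:1][CX4H1:2]([OX2H1:3])[#6:4]	1
T23	ketone reduction (secondary alcohol from ketone)	[#6:1][CX4H1:2]([OX2H1:3])[#6:4]>>[#6:1][CX3:2](=[O:3])[#6:4]	1
T24	Grignard addition (tertiary alcohol from ketone)	[#6:1][C:2]([OX2H1:3])([CX4;H3:4])[#6:5]>>[#6:1][C:2](=[O:3])[#6:5].[Br][Mg][CX4H3:4]	2
T25	Appel bromination (alkyl bromide from alcohol)	[CX4;!$(C[O,N,S]):1][Br]>>[CX4:1][OX2H1]	1
T26	cyanation (nitrile from alkyl bromide)	[#6:1][CX4;H2:2][C;+0:3]#[N:4]>>[#6:1][CX4H2:2][Br].[C-:3]#[N:4]	2
T27	ester saponification (acid from methyl ester)	[CX3;!$(C[N,S]):1](=[O:2])[OX2H1:3]>>[C:1](=[O:2])[OX2:3][CH3]	1
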