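# Pichia pastoris central carbon metabolism -- possMFA reaction table
# Simplified stoichiometric model for growth on glucose, glycerol and methanol:
# EMP glycolysis, TCA cycle with glyoxylate shunt, pentose phosphate pathway,
# fermentative branch, methanol oxidation/assimilation (XuMP), glycerol uptake,
# with cytosolic/mitochondrial pools for pyruvate, acetyl-CoA, OAA, NAD(P)H.
# Energy cofactors (ATP) are deliberately not balanced.  Reduced cofactor
# forms only are balanced (oxidised partners implicit).  Fluxes in
# mol kg-1 DW h-1; the biomass reaction is scaled to 1 Cmol biomass per unit
# flux.  Reaction numbering is 1-based; reversibility is encoded by the
# arrow (`<->` reversible, `->` irreversible).
[metabolites]
id	internal	carbons	name
GLC.e	0	6	glucose (extracellular)
GLOL.e	0	3	glycerol (extracellular)
MEOH.e	0	1	methanol (extracellular)
ETOH.e	0	2	ethanol (extracellular)
O2.e	0	0	molecular oxygen (extracellular)
CO2.e	0	1	carbon dioxide (extracellular)
H2O.e	0	0	water (extracellular)
NH3.e	0	0	ammonia / nitrogen source (extracellular)
BIOM.e	0	1	biomass (1 Cmol dry weight)
G6P	1	6	glucose 6-phosphate
F6P	1	6	fructose 6-phosphate
FBP	1	6	fructose 1,6-bisphosphate
DHAP	1	3	dihydroxyacetone phosphate
GAP	1	3	glyceraldehyde 3-phosphate
PG3	1	3	3-phosphoglycerate
PEP	1	3	phosphoenolpyruvate
PYR.c	1	3	pyruvate (cytosolic)
ACD	1	2	acetaldehyde
ACCOA.c	1	2	acetyl-CoA (cytosolic)
OAA.c	1	4	oxaloacetate (cytosolic)
MAL.c	1	4	malate (cytosolic)
NADH.c	1	0	NADH (cytosolic)
NADPH.c	1	0	NADPH (cytosolic)
P6G	1	6	6-phosphogluconate
RU5P	1	5	ribulose 5-phosphate
XU5P	1	5	xylulose 5-phosphate
R5P	1	5	ribose 5-phosphate
S7P	1	7	sedoheptulose 7-phosphate
E4P	1	4	erythrose 4-phosphate
FALD	1	1	formaldehyde
FORM	1	1	formate
DHA	1	3	dihydroxyacetone
G3P	1	3	glycerol 3-phosphate
PYR.m	1	3	pyruvate (mitochondrial)
ACCOA.m	1	2	acetyl-CoA (mitochondrial)
OAA.m	1	4	oxaloacetate (mitochondrial)
CIT.m	1	6	citrate (mitochondrial)
ICIT.m	1	6	isocitrate (mitochondrial)
AKG.m	1	5	2-oxoglutarate (mitochondrial)
SUC.m	1	4	succinate (mitochondrial)
MAL.m	1	4	malate (mitochondrial)
GLX.m	1	2	glyoxylate (mitochondrial)
NADH.m	1	0	NADH (mitochondrial)
NADPH.m	1	0	NADPH (mitochondrial)
FADH2.m	1	0	FADH2 (mitochondrial)
[reactions]
id	equation	name
v01	GLC.e -> G6P	glucose uptake + hexokinase
v02	G6P <-> F6P	phosphoglucose isomerase
v03	F6P <-> FBP	phosphofructokinase / FBPase (lumped)
v04	FBP <-> DHAP + GAP	fructose-bisphosphate aldolase
v05	DHAP <-> GAP	triose-phosphate isomerase
v06	GAP <-> PG3 + NADH.c	GAPDH + phosphoglycerate kinase (lumped)
v07	PG3 <-> PEP	phosphoglycerate mutase + enolase
v08	PEP <-> PYR.c	pyruvate kinase / PEP synthesis (lumped)
v09	PYR.c -> ACD + CO2.e	pyruvate decarboxylase
v10	ACD + NADH.c -> ETOH.e	alcohol dehydrogenase (ethanol formation)
v11	ACD -> ACCOA.c + NADH.c	acetaldehyde dehydrogenase + acetyl-CoA synthetase (lumped)
v12	PYR.m -> ACCOA.m + CO2.e + NADH.m	pyruvate dehydrogenase
v13	ACCOA.m + OAA.m -> CIT.m	citrate synthase
v14	CIT.m -> ICIT.m	aconitase
v15	PYR.c <-> PYR.m	mitochondrial pyruvate transport
v16	ICIT.m -> AKG.m + CO2.e + NADH.m	isocitrate dehydrogenase (NAD)
v17	AKG.m -> SUC.m + CO2.e + NADH.m	2-oxoglutarate dehydrogenase + succinyl-CoA synthetase
v18	SUC.m -> MAL.m + FADH2.m	succinate dehydrogenase + fumarase (lumped)
v19	MAL.m -> OAA.m + NADH.m	malate dehydrogenase (mitochondrial)
v20	G6P -> P6G + NADPH.c	glucose-6-phosphate dehydrogenase + lactonase
v21	P6G -> RU5P + CO2.e + NADPH.c	6-phosphogluconate dehydrogenase
v22	RU5P <-> R5P	ribose-5-phosphate isomerase
v23	RU5P <-> XU5P	ribulose-5-phosphate epimerase
v24	XU5P + R5P <-> S7P + GAP	transketolase 1
v25	S7P + GAP <-> E4P + F6P	transaldolase
v26	XU5P + E4P <-> F6P + GAP	transketolase 2
v27	OAA.c + NADH.c <-> MAL.c	malate dehydrogenase (cytosolic)
v28	ICIT.m -> SUC.m + GLX.m	isocitrate lyase
v29	MAL.c <-> MAL.m	mitochondrial malate transport
v30	GLX.m + ACCOA.m -> MAL.m	malate synthase
v31	MEOH.e + 0.5 O2.e -> FALD + H2O.e	alcohol oxidase + catalase (lumped)
v32	XU5P + FALD -> DHA + GAP	dihydroxyacetone synthase
v33	FALD -> FORM + NADH.c	formaldehyde dehydrogenase + S-formylglutathione hydrolase
v34	FORM <-> CO2.e + NADH.c	formate dehydrogenase
v35	DHA -> DHAP	dihydroxyacetone kinase
v36	ICIT.m -> AKG.m + CO2.e + NADPH.m	isocitrate dehydrogenase (NADP)
v37	NADH.c + 0.5 O2.e -> H2O.e	external NADH dehydrogenase + respiratory chain
v38	NADH.m + 0.5 O2.e -> H2O.e	internal NADH dehydrogenase + respiratory chain
v39	FADH2.m + 0.5 O2.e -> H2O.e	FADH2 oxidation via respiratory chain
v40	ACCOA.c -> ACCOA.m	acetyl-CoA transport (carnitine shuttle)
v41	GLOL.e <-> G3P	glycerol uptake + glycerol kinase (lumped)
v42	G3P -> DHAP + FADH2.m	glycerol-3-phosphate dehydrogenase (FAD, mitochondrial)
v43	DHAP + NADH.c -> G3P	glycerol-3-phosphate dehydrogenase (NAD, cytosolic)
v44	0.07 G6P + 0.012 R5P + 0.01 E4P + 0.015 PEP + 0.05 PYR.c + 0.04 ACCOA.c + 0.03 ACCOA.m + 0.02125 OAA.c + 0.012 AKG.m + 0.1136 NADPH.c + 0.01 NADPH.m + 0.15 NH3.e -> BIOM.e	biomass synthesis (lumped, 1 Cmol DW)
[exchanges]
quantity	metabolite	direction
glucose	GLC.e	uptake
glycerol	GLOL.e	uptake
methanol	MEOH.e	uptake
ethanol	ETOH.e	production
o2	O2.e	uptake
co2	CO2.e	production
biomass	BIOM.e	production
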