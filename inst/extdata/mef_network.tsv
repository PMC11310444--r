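# Compartmentalized MEF central-carbon network for 13C-MFA.
# Reconstruction from the published flux map and methods description:
# three compartments (extracellular .x, cytosol .c, mitochondrion .m) plus a
# virtual measurement compartment (.meas) for GC-MS pools homogenized at
# extraction. The exact reaction list of the original Metran model is not
# public; this network reproduces its documented structure (glycolysis, oxPPP
# and non-oxPPP, TCA cycle, PC anaplerosis, ME1/ME2, MDH1/MDH2, PCK1,
# cytosolic/mitochondrial pools for pyr, accoa, cit, akg, mal, oac, ala, glu,
# asp, mixing reactions for the six dually compartmented measured metabolites,
# unlabeled-CO2 fixation and unlabeled medium dilution inflows for glutamate,
# aspartate and pyruvate).
# columns: reaction_id<TAB>reversible<TAB>kind<TAB>equation
@symmetric	suc.m
HK	0	exchange	glc.x (abcdef) -> g6p.c (abcdef)
PGI	1	enzymatic	g6p.c (abcdef) -> f6p.c (abcdef)
PFK	0	enzymatic	f6p.c (abcdef) -> fbp.c (abcdef)
ALD	0	enzymatic	fbp.c (abcdef) -> dhap.c (cba) + gap.c (def)
TPI	1	enzymatic	dhap.c (abc) -> gap.c (abc)
GAPD	0	enzymatic	gap.c (abc) -> 3pg.c (abc)
ENO	0	enzymatic	3pg.c (abc) -> pep.c (abc)
PK	0	enzymatic	pep.c (abc) -> pyr.c (abc)
LDH	1	enzymatic	pyr.c (abc) -> lac.c (abc)
LACS	0	exchange	lac.c (abc) -> lac.x (abc)
G6PD	0	enzymatic	g6p.c (abcdef) -> ru5p.c (bcdef) + co2.x (a)
RPI	1	enzymatic	ru5p.c (abcde) -> r5p.c (abcde)
RPE	1	enzymatic	ru5p.c (abcde) -> x5p.c (abcde)
TKT1	1	enzymatic	x5p.c (abcde) + r5p.c (fghij) -> s7p.c (abfghij) + gap.c (cde)
TALA	1	enzymatic	s7p.c (abcdefg) + gap.c (hij) -> f6p.c (abchij) + e4p.c (defg)
TKT2	1	enzymatic	x5p.c (abcde) + e4p.c (fghi) -> f6p.c (abfghi) + gap.c (cde)
RNAS	0	exchange	r5p.c (abcde) -> rna.x (abcde)
GPD1	0	enzymatic	dhap.c (abc) -> g3p.c (abc)
LIPS	0	exchange	g3p.c (abc) -> lip.x (abc)
MPC	0	transport	pyr.c (abc) -> pyr.m (abc)
PDH	0	enzymatic	pyr.m (abc) -> accoa.m (bc) + co2.x (a)
PC	0	enzymatic	pyr.m (abc) + co2.x (d) -> oac.m (abcd)
CS	0	enzymatic	oac.m (abcd) + accoa.m (ef) -> cit.m (dcbfea)
IDH	0	enzymatic	cit.m (abcdef) -> akg.m (abcde) + co2.x (f)
AKGD	0	enzymatic	akg.m (abcde) -> suc.m (bcde) + co2.x (a)
SDH	0	enzymatic	suc.m (abcd) -> mal.m (abcd)
MDH2	1	enzymatic	mal.m (abcd) -> oac.m (abcd)
ME2	0	enzymatic	mal.m (abcd) -> pyr.m (abc) + co2.x (d)
MALT	1	transport	mal.m (abcd) -> mal.c (abcd)
CITT	0	transport	cit.m (abcdef) -> cit.c (abcdef)
ACL	0	enzymatic	cit.c (abcdef) -> oac.c (fcba) + accoa.c (ed)
FAS	0	exchange	accoa.c (ab) -> fas.x (ab)
MDH1	1	enzymatic	oac.c (abcd) -> mal.c (abcd)
ME1	0	enzymatic	mal.c (abcd) -> pyr.c (abc) + co2.x (d)
PCK1	0	enzymatic	oac.c (abcd) -> pep.c (abc) + co2.x (d)
GLNUP	0	exchange	gln.x (abcde) -> gln.c (abcde)
GLS	0	enzymatic	gln.c (abcde) -> glu.m (abcde)
GDH	0	enzymatic	glu.m (abcde) -> akg.m (abcde)
PROS	0	enzymatic	glu.m (abcde) -> pro.m (abcde)
PROSEC	0	exchange	pro.m (abcde) -> pro.x (abcde)
GOT2	1	enzymatic	oac.m (abcd) + glu.m (efghi) -> asp.m (abcd) + akg.m (efghi)
GOT1	1	enzymatic	oac.c (abcd) + glu.c (efghi) -> asp.c (abcd) + akg.c (efghi)
AKGT	0	transport	akg.m (abcde) -> akg.c (abcde)
GLUT	0	transport	glu.m (abcde) -> glu.c (abcde)
ASPT	0	transport	asp.m (abcd) -> asp.c (abcd)
ASPBM	0	exchange	asp.c (abcd) -> bm.x (abcd)
GLUBM	0	exchange	glu.c (abcde) -> glu_bm.x (abcde)
ALTM	0	enzymatic	pyr.m (abc) + glu.m (defgh) -> ala.m (abc) + akg.m (defgh)
ALAT	0	transport	ala.m (abc) -> ala.c (abc)
ALASEC	0	exchange	ala.c (abc) -> ala.x (abc)
DILGLU	0	dilution	glu_med.x (abcde) -> glu.c (abcde)
DILASP	0	dilution	asp_med.x (abcd) -> asp.c (abcd)
DILPYR	0	dilution	pyr_med.x (abc) -> pyr.c (abc)
MIXPYR	0	mixing	pyr.c + pyr.m -> pyr.meas
MIXALA	0	mixing	ala.c + ala.m -> ala.meas
MIXMAL	0	mixing	mal.c + mal.m -> mal.meas
MIXASP	0	mixing	asp.c + asp.m -> asp.meas
MIXAKG	0	mixing	akg.c + akg.m -> akg.meas
MIXCIT	0	mixing	cit.c + cit.m -> cit.meas
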