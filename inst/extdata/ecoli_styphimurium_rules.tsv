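# Regulatory rule strings from the published E. coli refinement and
# S. typhimurium transfer tables (original and refined forms), used as
# parser round-trip fixtures. Three entries are lightly repaired relative
# to the journal text (balanced parentheses, straight quotes).
target	rule	set
metINQ	(NOT MetJ)	original
glmU	(NagC)	original
glmU_r	(ON)	refined
ilvY	(NOT val-L(e)>0 )	original
ilvY_r	(ON)	refined
ilvC	(ilvY)	original
ilvC_r	(ilvY AND NOT (val-L(e)>0)) OR (NOT ilvY)	refined
sdaC	(Crp AND (NOT Lrp OR (leu-L(e)>0)))	original
sdaC_r	((Crp AND (NOT Lrp OR (leu-L(e)>0)))) OR (ser-L(e)>0)	refined
cycA	(NOT Lrp OR (leu-L(e)>0))	original
cycA_r	(NOT GcvB)	refined
gcvB_r	(NOT GcvR AND GcvA)	refined
rpiR	(NOT (rib-D(e)>0))	original
rpiR_r	(NOT ((all-D(e)>0) OR (rib-D(e)>0)))	refined
acnA	(SoxS)	original
acnA_r	(ON)	refined
ilvA	(NOT Lrp OR (leu-L(e)>0))	original
ilvA_r	(ON)	refined
argD	(NOT ArgR)	original
argD_r	(NOT ArgR) OR (arg-L(e)>0)	refined
astABCDE	((NOT(Growth>0) AND RpoS) OR (NRI_hi AND RpoN)) AND (NOT Lrp OR (leu-L(e)>0))	original
astABCDE_r	((NOT(Growth>0) AND RpoS) OR (NRI_hi AND RpoN))	refined
speA	(NOT (PurR))	original
speA_r	(NOT (PurR)) AND (NOT (AGMT>0))	refined
metH	(MetR)	original
metH_r	(metR) OR (met-L(e)>0)	refined
thrA	(NOT (thr-L(e)>0 OR ile-L(e)>0)) AND (NOT Lrp OR (leu-L(e)>0))	original
thrA_r	(NOT (thr-L(e)>0 OR ile-L(e)>0))	refined
rhaS	(RhaR)	original
rhaS_r	(RhaR OR (RhaR AND Crp))	refined
rhaR	(rmn(e)>0)	original
rhaR_r	(rmn(e)>0 OR lyx(e)>0 OR man(e))	refined
serC	(Lrp AND NOT (leu-L(e)>0) OR (NOT (Crp)))	original
serC_r	(ON)	refined
aroA	(Lrp AND NOT (leu-L(e)>0))	original
aroA_r	(ON)	refined
leuD	(NOT(leu-L(e)>0) AND Lrp)	original
leuD_r	(NOT(leu-L(e)>0))	refined
ilvB	(NOT(leu-L(e)>0 OR val-L(e)>0) AND Crp)	original
ilvB_r	(ON)	refined
dctA	(("CRP noMAN") AND NOT(ArcA) AND (DcuR))	original
dctA_r	(ON)	refined
prpB	(ppa(e)>0)	original
prpB_r	(PrpR AND RpoN AND (HimA AND HimD))	refined
prpR_r	(MCITS>0)	refined
himA_r	ON	refined
fadL	((NOT (Crp OR FadR OR OmpR)))	original
fadL_r	ON	refined
fucO	(((((FucR) OR (rmn(e)>0)) AND (NOT (o2(e)>0))) AND Crp) OR (((FucR) OR (rmn(e)>0)) AND (NOT (o2(e)>0))))	original
fucO_r	(fuc-L(e)>0 OR rmn(e)>0)	refined
glnA	(Crp AND RpoN)	original
glnA_r	ON	refined
ttdA	(NOT(o2(e)>0) AND (tartr-L(e)>0))	original
ttdA_r	(tartr-L(e)>0)	refined
focA	(ArcA OR Fnr AND (Crp OR NOT (NarL)))	original
focA_r	ON	refined
prsA	(NOT PurR)	original
prsA_r	ON	refined
guaA	(NOT (PurR AND Crp))	original
guaA_r	ON	refined
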