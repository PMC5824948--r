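# SYNTHETIC 201-node colorectal-cancer signalling network, rules mode.
# The published 201-node human signalling network (Cho et al. 2016) ships
# only as journal supplementary data, so this fixture is a synthetic
# benchmark of the same shape: 13 input nodes (held at their sampled
# value), a curated WNT / MAPK / PI3K / p53 / TGF-beta / JAK-STAT core,
# 8 output nodes, and five-deep transcriptional relay chains. Driver
# mutations are encoded as node fixing: APC 0, KRAS 1, PTEN 0, TP53 0
# (cumulative arms), plus RAS 1 and PI3K 1 for an HCT-116-like line.
# Designed behavior under sampled rules-based DA: normal-proliferation
# propensity is non-increasing and combined abnormal-fate propensity
# non-decreasing across the cumulative driver arms.
node,initial_state,basal_value
EGF,0,0
IGF,0,0
HGF,0,0
WNT,0,0
TGFB,0,0
DNA_DAM,0,0
HYPOXIA,0,0
NUTRIENT,0,0
FASL,0,0
IL6,0,0
NOTCHL,0,0
OXSTRESS,0,0
BMP,0,0
EGFR,0,0
IGFR,0,0
METR,0,0
SPRY,0,0
RAS,0,0
KRAS,0,0
RAF,0,0
MEK,0,0
ERK,0,0
PI3K,0,0
PTEN,0,0
AKT,0,0
DVL,0,0
GSK3B,0,0
APC,0,0
BCAT,0,0
MYC,0,0
ONCO,0,0
CYCD,0,0
CDK46,0,0
RB,0,0
E2F,0,0
CYCE,0,0
ATM,0,0
MDM2,0,0
TP53,0,0
P21,0,0
BAX,0,0
IL6R,0,0
STAT3,0,0
BCL2,0,0
CASP8,0,0
CASP9,0,0
IAP,0,0
CASP3,0,0
SMAD,0,0
SNAIL,0,0
ECAD,0,0
VIM,0,0
HIF1,0,0
VEGF,0,0
NOTCHR,0,0
HES1,0,0
SMAD15,0,0
ID1,0,0
PROLIF,0,0
APOP,0,0
ARREST,0,0
EMT,0,0
MIG,0,0
ANGIO,0,0
DIFF,0,0
SEN,0,0
ERK_T1,0,0
ERK_T2,0,0
ERK_T3,0,0
ERK_T4,0,0
ERK_T5,0,0
AKT_T1,0,0
AKT_T2,0,0
AKT_T3,0,0
AKT_T4,0,0
AKT_T5,0,0
BCAT_T1,0,0
BCAT_T2,0,0
BCAT_T3,0,0
BCAT_T4,0,0
BCAT_T5,0,0
TP53_T1,0,0
TP53_T2,0,0
TP53_T3,0,0
TP53_T4,0,0
TP53_T5,0,0
MYC_T1,0,0
MYC_T2,0,0
MYC_T3,0,0
MYC_T4,0,0
MYC_T5,0,0
SNAIL_T1,0,0
SNAIL_T2,0,0
SNAIL_T3,0,0
SNAIL_T4,0,0
SNAIL_T5,0,0
STAT3_T1,0,0
STAT3_T2,0,0
STAT3_T3,0,0
STAT3_T4,0,0
STAT3_T5,0,0
HIF1_T1,0,0
HIF1_T2,0,0
HIF1_T3,0,0
HIF1_T4,0,0
HIF1_T5,0,0
HES1_T1,0,0
HES1_T2,0,0
HES1_T3,0,0
HES1_T4,0,0
HES1_T5,0,0
ID1_T1,0,0
ID1_T2,0,0
ID1_T3,0,0
ID1_T4,0,0
ID1_T5,0,0
CASP3_T1,0,0
CASP3_T2,0,0
CASP3_T3,0,0
CASP3_T4,0,0
CASP3_T5,0,0
P21_T1,0,0
P21_T2,0,0
P21_T3,0,0
P21_T4,0,0
P21_T5,0,0
CYCE_T1,0,0
CYCE_T2,0,0
CYCE_T3,0,0
CYCE_T4,0,0
CYCE_T5,0,0
E2F_T1,0,0
E2F_T2,0,0
E2F_T3,0,0
E2F_T4,0,0
E2F_T5,0,0
VEGF_T1,0,0
VEGF_T2,0,0
VEGF_T3,0,0
VEGF_T4,0,0
VEGF_T5,0,0
SMAD_T1,0,0
SMAD_T2,0,0
SMAD_T3,0,0
SMAD_T4,0,0
SMAD_T5,0,0
KRAS_T1,0,0
KRAS_T2,0,0
KRAS_T3,0,0
KRAS_T4,0,0
KRAS_T5,0,0
PI3K_T1,0,0
PI3K_T2,0,0
PI3K_T3,0,0
PI3K_T4,0,0
PI3K_T5,0,0
BAX_T1,0,0
BAX_T2,0,0
BAX_T3,0,0
BAX_T4,0,0
BAX_T5,0,0
BCL2_T1,0,0
BCL2_T2,0,0
BCL2_T3,0,0
BCL2_T4,0,0
BCL2_T5,0,0
MDM2_T1,0,0
MDM2_T2,0,0
MDM2_T3,0,0
MDM2_T4,0,0
MDM2_T5,0,0
ATM_T1,0,0
ATM_T2,0,0
ATM_T3,0,0
ATM_T4,0,0
ATM_T5,0,0
GSK3B_T1,0,0
GSK3B_T2,0,0
GSK3B_T3,0,0
GSK3B_T4,0,0
GSK3B_T5,0,0
ECAD_T1,0,0
ECAD_T2,0,0
ECAD_T3,0,0
ECAD_T4,0,0
ECAD_T5,0,0
VIM_T1,0,0
VIM_T2,0,0
VIM_T3,0,0
VIM_T4,0,0
VIM_T5,0,0
IAP_T1,0,0
IAP_T2,0,0
IAP_T3,0,0
IAP_T4,0,0
IAP_T5,0,0
ONCO_T1,0,0
ONCO_T2,0,0
ONCO_T3,0,0
ONCO_T4,0,0
ONCO_T5,0,0
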