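# Update rules for the synthetic CRC network. Input nodes keep their
# sampled value via explicit identity rules.
EGF = EGF
IGF = IGF
HGF = HGF
WNT = WNT
TGFB = TGFB
DNA_DAM = DNA_DAM
HYPOXIA = HYPOXIA
NUTRIENT = NUTRIENT
FASL = FASL
IL6 = IL6
NOTCHL = NOTCHL
OXSTRESS = OXSTRESS
BMP = BMP
EGFR = EGF
IGFR = IGF
METR = HGF
SPRY = ERK
RAS = (EGFR OR IGFR OR METR) AND NOT SPRY
KRAS = RAS
RAF = KRAS
MEK = RAF
ERK = MEK
PI3K = KRAS OR IGFR
PTEN = 1
AKT = PI3K AND NOT PTEN
DVL = WNT
GSK3B = NOT AKT AND NOT DVL
APC = 1
BCAT = NOT APC OR (DVL AND NOT GSK3B)
MYC = BCAT OR ERK
ONCO = (BCAT AND NOT WNT) OR (ERK AND NOT EGF AND NOT IGF AND NOT HGF) OR (ATM AND NOT TP53 AND NOT MDM2)
CYCD = (ERK OR BCAT) AND NOT P21
CDK46 = CYCD
RB = NOT CDK46
E2F = NOT RB
CYCE = E2F AND NOT P21
ATM = DNA_DAM
MDM2 = AKT AND NOT ATM
TP53 = ATM AND NOT MDM2
P21 = TP53
BAX = TP53
IL6R = IL6
STAT3 = IL6R
BCL2 = AKT OR STAT3
CASP8 = FASL
CASP9 = BAX AND NOT BCL2
IAP = AKT OR STAT3
CASP3 = CASP9 AND CASP8 AND NOT IAP
SMAD = TGFB
SNAIL = (SMAD AND ERK) OR (BCAT AND AKT)
ECAD = NOT SNAIL
VIM = SNAIL
HIF1 = HYPOXIA
VEGF = HIF1 OR AKT
NOTCHR = NOTCHL
HES1 = NOTCHR
SMAD15 = BMP
ID1 = SMAD15
PROLIF = CYCE AND MYC AND NUTRIENT
APOP = CASP3
ARREST = P21 AND NOT CASP3
EMT = SNAIL AND VIM AND NOT ECAD
MIG = EMT AND ERK
ANGIO = VEGF AND HIF1
DIFF = HES1 AND NOT MYC
SEN = P21 AND OXSTRESS
ERK_T1 = ERK
ERK_T2 = ERK_T1
ERK_T3 = ERK_T2
ERK_T4 = ERK_T3
ERK_T5 = ERK_T4
AKT_T1 = AKT
AKT_T2 = AKT_T1
AKT_T3 = AKT_T2
AKT_T4 = AKT_T3
AKT_T5 = AKT_T4
BCAT_T1 = BCAT
BCAT_T2 = BCAT_T1
BCAT_T3 = BCAT_T2
BCAT_T4 = BCAT_T3
BCAT_T5 = BCAT_T4
TP53_T1 = TP53
TP53_T2 = TP53_T1
TP53_T3 = TP53_T2
TP53_T4 = TP53_T3
TP53_T5 = TP53_T4
MYC_T1 = MYC
MYC_T2 = MYC_T1
MYC_T3 = MYC_T2
MYC_T4 = MYC_T3
MYC_T5 = MYC_T4
SNAIL_T1 = SNAIL
SNAIL_T2 = SNAIL_T1
SNAIL_T3 = SNAIL_T2
SNAIL_T4 = SNAIL_T3
SNAIL_T5 = SNAIL_T4
STAT3_T1 = STAT3
STAT3_T2 = STAT3_T1
STAT3_T3 = STAT3_T2
STAT3_T4 = STAT3_T3
STAT3_T5 = STAT3_T4
HIF1_T1 = HIF1
HIF1_T2 = HIF1_T1
HIF1_T3 = HIF1_T2
HIF1_T4 = HIF1_T3
HIF1_T5 = HIF1_T4
HES1_T1 = HES1
HES1_T2 = HES1_T1
HES1_T3 = HES1_T2
HES1_T4 = HES1_T3
HES1_T5 = HES1_T4
ID1_T1 = ID1
ID1_T2 = ID1_T1
ID1_T3 = ID1_T2
ID1_T4 = ID1_T3
ID1_T5 = ID1_T4
CASP3_T1 = CASP3
CASP3_T2 = CASP3_T1
CASP3_T3 = CASP3_T2
CASP3_T4 = CASP3_T3
CASP3_T5 = CASP3_T4
P21_T1 = P21
P21_T2 = P21_T1
P21_T3 = P21_T2
P21_T4 = P21_T3
P21_T5 = P21_T4
CYCE_T1 = CYCE
CYCE_T2 = CYCE_T1
CYCE_T3 = CYCE_T2
CYCE_T4 = CYCE_T3
CYCE_T5 = CYCE_T4
E2F_T1 = E2F
E2F_T2 = E2F_T1
E2F_T3 = E2F_T2
E2F_T4 = E2F_T3
E2F_T5 = E2F_T4
VEGF_T1 = VEGF
VEGF_T2 = VEGF_T1
VEGF_T3 = VEGF_T2
VEGF_T4 = VEGF_T3
VEGF_T5 = VEGF_T4
SMAD_T1 = SMAD
SMAD_T2 = SMAD_T1
SMAD_T3 = SMAD_T2
SMAD_T4 = SMAD_T3
SMAD_T5 = SMAD_T4
KRAS_T1 = KRAS
KRAS_T2 = KRAS_T1
KRAS_T3 = KRAS_T2
KRAS_T4 = KRAS_T3
KRAS_T5 = KRAS_T4
PI3K_T1 = PI3K
PI3K_T2 = PI3K_T1
PI3K_T3 = PI3K_T2
PI3K_T4 = PI3K_T3
PI3K_T5 = PI3K_T4
BAX_T1 = BAX
BAX_T2 = BAX_T1
BAX_T3 = BAX_T2
BAX_T4 = BAX_T3
BAX_T5 = BAX_T4
BCL2_T1 = BCL2
BCL2_T2 = BCL2_T1
BCL2_T3 = BCL2_T2
BCL2_T4 = BCL2_T3
BCL2_T5 = BCL2_T4
MDM2_T1 = MDM2
MDM2_T2 = MDM2_T1
MDM2_T3 = MDM2_T2
MDM2_T4 = MDM2_T3
MDM2_T5 = MDM2_T4
ATM_T1 = ATM
ATM_T2 = ATM_T1
ATM_T3 = ATM_T2
ATM_T4 = ATM_T3
ATM_T5 = ATM_T4
GSK3B_T1 = GSK3B
GSK3B_T2 = GSK3B_T1
GSK3B_T3 = GSK3B_T2
GSK3B_T4 = GSK3B_T3
GSK3B_T5 = GSK3B_T4
ECAD_T1 = ECAD
ECAD_T2 = ECAD_T1
ECAD_T3 = ECAD_T2
ECAD_T4 = ECAD_T3
ECAD_T5 = ECAD_T4
VIM_T1 = VIM
VIM_T2 = VIM_T1
VIM_T3 = VIM_T2
VIM_T4 = VIM_T3
VIM_T5 = VIM_T4
IAP_T1 = IAP
IAP_T2 = IAP_T1
IAP_T3 = IAP_T2
IAP_T4 = IAP_T3
IAP_T5 = IAP_T4
ONCO_T1 = ONCO
ONCO_T2 = ONCO_T1
ONCO_T3 = ONCO_T2
ONCO_T4 = ONCO_T3
ONCO_T5 = ONCO_T4
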