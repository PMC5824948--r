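#!/usr/bin/env Rscript
# Regenerates the synthetic fixtures bundled under inst/extdata/.
# Run from the package root:  Rscript tools/make_fixtures.R
#
# yeast11_network.txt is a hand transcription of a published network and is
# NOT written by this script. The MCF-7 p53 fixture and the 201-node CRC
# fixture are synthetic benchmarks designed here (see the files' header
# comments and the methods vignette for the design rationale).

out <- function(...) file.path("inst", "extdata", ...)

## ---- synthetic MCF-7 p53 network ------------------------------------------

mcf7_header <- c(
"# SYNTHETIC 16-node p53-signalling network for the MCF-7 treatment case",
"# study. The published weighted network (Choi et al. 2012, Sci. Signal.",
"# 5:ra83) is only available as journal supplementary data, so this fixture",
"# is a stand-in built from the same circuitry: ATM -> p53 activation with",
"# the Wip1 and MDM2 negative feedbacks, the p53 -> PTEN -> AKT -> MDM2",
"# positive feedback, a BCL2-gated BAX/caspase death switch with an",
"# absorbing committed state, and a p21/14-3-3sigma/Rb arrest arm.",
"# Treatments are encoded exactly as in the case study: Etoposide (E) sets",
"# the basal value of ATM to 1, WIP1 knock-down (W) sets the basal value of",
"# WIP1 to -1000, and Nutlin (N) deletes the MDM2 -> P53 interaction.",
"# Designed behavior (exhaustive DA over 2^16 states): untreated control",
"# converges to a single proliferation attractor; apoptotic basin share is",
"# strictly ordered E+N+W > N+W > E+N > N > E+W > E, with W alone inert.")

mcf7_network <- c(
"node,initial_state,basal_value",
"ATM,0,0", "P53,0,1", "MDM2,1,1", "WIP1,0,0", "PTEN,0,0", "AKT,1,1",
"CYCG,0,0", "P21,0,0", "SFN,0,0", "CYCE,1,0", "E2F1,1,1", "RB,0,1",
"BAX,0,0", "BCL2,1,-0.5", "AIP1,0,-1", "CASP,0,-1.5",
"source,target,weight,type",
"WIP1,ATM,-1,inhibition", "ATM,ATM,-0.1,inhibition",
"MDM2,P53,-2.5,inhibition", "WIP1,P53,-1,inhibition", "ATM,P53,1,activation",
"P53,MDM2,1,activation", "AKT,MDM2,1,activation", "CYCG,MDM2,1,activation",
"ATM,MDM2,-1,inhibition",
"P53,WIP1,1,activation", "WIP1,WIP1,-0.1,inhibition",
"P53,PTEN,1,activation", "PTEN,PTEN,-0.1,inhibition",
"PTEN,AKT,-2,inhibition",
"P53,CYCG,1,activation", "CYCG,CYCG,-0.1,inhibition",
"P53,P21,2,activation", "AKT,P21,-1,inhibition", "P21,P21,-0.1,inhibition",
"P53,SFN,1,activation", "SFN,SFN,-0.1,inhibition",
"E2F1,CYCE,1,activation", "P21,CYCE,-2,inhibition", "SFN,CYCE,-1,inhibition",
"RB,E2F1,-2,inhibition",
"CYCE,RB,-2,inhibition", "AKT,RB,-2,inhibition",
"P53,BAX,2,activation", "BCL2,BAX,-1,inhibition", "BAX,BAX,-0.1,inhibition",
"AKT,BCL2,1,activation", "BCL2,BCL2,0.6,activation", "CASP,BCL2,-2,inhibition",
"P53,AIP1,1,activation", "ATM,AIP1,1,activation", "WIP1,AIP1,-1,inhibition",
"BAX,CASP,1,activation", "AIP1,CASP,1,activation", "BCL2,CASP,-2,inhibition",
"CASP,CASP,1.4,activation")

writeLines(c(mcf7_header, mcf7_network), out("mcf7_p53_synthetic_network.csv"))

mcf7_perts <- list(
  E   = "BASAL ATM 1",
  N   = "DELETE_EDGE MDM2 P53",
  W   = "BASAL WIP1 -1000",
  EN  = c("BASAL ATM 1", "DELETE_EDGE MDM2 P53"),
  EW  = c("BASAL ATM 1", "BASAL WIP1 -1000"),
  NW  = c("DELETE_EDGE MDM2 P53", "BASAL WIP1 -1000"),
  ENW = c("BASAL ATM 1", "DELETE_EDGE MDM2 P53", "BASAL WIP1 -1000"))
for (nm in names(mcf7_perts)) {
  writeLines(c(sprintf("# MCF-7 treatment arm %s", nm), mcf7_perts[[nm]]),
             out(sprintf("mcf7_pert_%s.txt", nm)))
}

writeLines(c(
"# Fate logic for the synthetic MCF-7 p53 network (first matching rule wins).",
"FATE apoptosis: CASP",
"FATE senescence: P21 OR SFN OR RB",
"FATE proliferation: CYCE"), out("mcf7_fates.txt"))

## ---- synthetic 201-node CRC signalling network (rules mode) ----------------

inputs <- c("EGF", "IGF", "HGF", "WNT", "TGFB", "DNA_DAM", "HYPOXIA",
            "NUTRIENT", "FASL", "IL6", "NOTCHL", "OXSTRESS", "BMP")

core_rules <- c(
  "EGFR = EGF",
  "IGFR = IGF",
  "METR = HGF",
  "SPRY = ERK",
  "RAS = (EGFR OR IGFR OR METR) AND NOT SPRY",
  "KRAS = RAS",
  "RAF = KRAS",
  "MEK = RAF",
  "ERK = MEK",
  "PI3K = KRAS OR IGFR",
  "PTEN = 1",
  "AKT = PI3K AND NOT PTEN",
  "DVL = WNT",
  "GSK3B = NOT AKT AND NOT DVL",
  "APC = 1",
  "BCAT = NOT APC OR (DVL AND NOT GSK3B)",
  "MYC = BCAT OR ERK",
  "ONCO = (BCAT AND NOT WNT) OR (ERK AND NOT EGF AND NOT IGF AND NOT HGF) OR (ATM AND NOT TP53 AND NOT MDM2)",
  "CYCD = (ERK OR BCAT) AND NOT P21",
  "CDK46 = CYCD",
  "RB = NOT CDK46",
  "E2F = NOT RB",
  "CYCE = E2F AND NOT P21",
  "ATM = DNA_DAM",
  "MDM2 = AKT AND NOT ATM",
  "TP53 = ATM AND NOT MDM2",
  "P21 = TP53",
  "BAX = TP53",
  "IL6R = IL6",
  "STAT3 = IL6R",
  "BCL2 = AKT OR STAT3",
  "CASP8 = FASL",
  "CASP9 = BAX AND NOT BCL2",
  "IAP = AKT OR STAT3",
  "CASP3 = CASP9 AND CASP8 AND NOT IAP",
  "SMAD = TGFB",
  "SNAIL = (SMAD AND ERK) OR (BCAT AND AKT)",
  "ECAD = NOT SNAIL",
  "VIM = SNAIL",
  "HIF1 = HYPOXIA",
  "VEGF = HIF1 OR AKT",
  "NOTCHR = NOTCHL",
  "HES1 = NOTCHR",
  "SMAD15 = BMP",
  "ID1 = SMAD15")

output_rules <- c(
  "PROLIF = CYCE AND MYC AND NUTRIENT",
  "APOP = CASP3",
  "ARREST = P21 AND NOT CASP3",
  "EMT = SNAIL AND VIM AND NOT ECAD",
  "MIG = EMT AND ERK",
  "ANGIO = VEGF AND HIF1",
  "DIFF = HES1 AND NOT MYC",
  "SEN = P21 AND OXSTRESS")

relay_sources <- c("ERK", "AKT", "BCAT", "TP53", "MYC", "SNAIL", "STAT3",
                   "HIF1", "HES1", "ID1", "CASP3", "P21", "CYCE", "E2F",
                   "VEGF", "SMAD", "KRAS", "PI3K", "BAX", "BCL2", "MDM2",
                   "ATM", "GSK3B", "ECAD", "VIM", "IAP", "ONCO")
relay_rules <- unlist(lapply(relay_sources, function(x) {
  sprintf("%s_T%d = %s", x, 1:5, c(x, sprintf("%s_T%d", x, 1:4)))
}))

rule_name <- function(r) sub(" =.*$", "", r)
core_nodes <- rule_name(core_rules)
output_nodes <- rule_name(output_rules)
relay_nodes <- rule_name(relay_rules)
all_nodes <- c(inputs, core_nodes, output_nodes, relay_nodes)
stopifnot(length(all_nodes) == 201L, !anyDuplicated(all_nodes))

crc_header <- c(
"# SYNTHETIC 201-node colorectal-cancer signalling network, rules mode.",
"# The published 201-node human signalling network (Cho et al. 2016) ships",
"# only as journal supplementary data, so this fixture is a synthetic",
"# benchmark of the same shape: 13 input nodes (held at their sampled",
"# value), a curated WNT / MAPK / PI3K / p53 / TGF-beta / JAK-STAT core,",
"# 8 output nodes, and five-deep transcriptional relay chains. Driver",
"# mutations are encoded as node fixing: APC 0, KRAS 1, PTEN 0, TP53 0",
"# (cumulative arms), plus RAS 1 and PI3K 1 for an HCT-116-like line.",
"# Designed behavior under sampled rules-based DA: normal-proliferation",
"# propensity is non-increasing and combined abnormal-fate propensity",
"# non-decreasing across the cumulative driver arms.")

writeLines(c(crc_header, "node,initial_state,basal_value",
             sprintf("%s,0,0", all_nodes)),
           out("crc201_synthetic_network.csv"))

writeLines(c(
"# Update rules for the synthetic CRC network. Input nodes keep their",
"# sampled value via explicit identity rules.",
sprintf("%s = %s", inputs, inputs),
core_rules, output_rules, relay_rules), out("crc201_synthetic_rules.txt"))

crc_perts <- list(
  A    = "FIX APC 0",
  AK   = c("FIX APC 0", "FIX KRAS 1"),
  AKP  = c("FIX APC 0", "FIX KRAS 1", "FIX PTEN 0"),
  AKPT = c("FIX APC 0", "FIX KRAS 1", "FIX PTEN 0", "FIX TP53 0"),
  HCT116 = c("FIX RAS 1", "FIX PI3K 1"))
for (nm in names(crc_perts)) {
  writeLines(c(sprintf("# CRC driver arm %s", nm), crc_perts[[nm]]),
             out(sprintf("crc201_pert_%s.txt", nm)))
}

writeLines(c(
"# Fate logic for the synthetic CRC network. Order expresses precedence:",
"# tumor progression (abnormal proliferation concurrent with metastasis)",
"# must be matched before its component fates.",
"FATE apoptosis: APOP",
"FATE tumor_progression: PROLIF AND ONCO AND EMT",
"FATE abnormal_proliferation: PROLIF AND ONCO",
"FATE normal_proliferation: PROLIF",
"FATE metastasis: EMT",
"FATE arrest: ARREST OR SEN"), out("crc201_fates.txt"))

cat("fixtures written to inst/extdata/\n")
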