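# Shared axis vocabularies. The penetrance age axis runs 1..MAX_AGE; ages in
# input pedigrees beyond MAX_AGE are clamped during pedigree checking because
# penetrance values are undefined past the axis end.
MAX_AGE <- 94L

RACES <- c("All_Races", "AIAN", "Asian", "Black", "White", "Hispanic", "WH", "WNH")
ANCESTRIES <- c("AJ", "nonAJ", "Italian")
SEXES <- c("Female", "Male")
PENET_TYPES <- c("Net", "Crude")
MARKERS <- c("CK14", "CK5.6", "ER", "PR", "HER2", "MSI")

# Short cancer tags used as isAff*/Age* column suffixes, mapped to the full
# cancer labels used on the penetrance axis. A copy travels inside every
# parameter database so user databases can extend it.
CANCER_TAGS <- c(
  BRA  = "Brain",
  BC   = "Breast",
  CER  = "Cervical",
  COL  = "Colorectal",
  ENDO = "Endometrial",
  GAS  = "Gastric",
  HEP  = "Hepatobiliary",
  KID  = "Kidney",
  LEUK = "Leukemia",
  MELA = "Melanoma",
  OST  = "Osteosarcoma",
  OC   = "Ovarian",
  PANC = "Pancreatic",
  SMA  = "SmallIntestine",
  STS  = "SoftTissueSarcoma",
  THY  = "Thyroid",
  UB   = "UrinaryBladder"
)

# Susceptibility genes known to the toy database builder.
PANEL_GENES <- c(
  "APC", "ATM", "BARD1", "BMPR1A", "BRCA1", "BRCA2", "BRIP1", "CDH1",
  "CDK4", "CDKN2A", "CHEK2", "EPCAM", "MLH1", "MSH2", "MSH6", "MUTYH",
  "NBN", "PALB2", "PMS2", "PTEN", "RAD51C", "RAD51D", "STK11", "TP53"
)

# Cancers with penetrance support restricted to one sex in the toy databases.
FEMALE_ONLY_CANCERS <- c("Ovarian", "Endometrial", "Cervical")

NONCARRIER <- "noncarrier"

variant_label <- function(gene) paste0(gene, "_hetero_anyPV")

mr_error <- function(msg, class) {
  abort(msg, class = c(class, "mendelrisk_error"))
}
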