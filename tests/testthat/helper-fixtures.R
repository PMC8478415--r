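# Fixtures built in code: flat-curve databases with known arithmetic, and
# small pedigree topologies.

# Database whose per-age net penetrance is constant (p_carrier for every
# carrier state, p_noncarrier for the baseline), crude = net * crude_ratio.
# Flat curves make censoring-likelihood and risk arithmetic closed-form.
const_db <- function(genes = "BRCA1", cancers = "Breast",
                     p_carrier = 0.002, p_noncarrier = 5e-4,
                     crude_ratio = 1, freq = 0.01, female_only = FALSE) {
  K <- length(genes)
  R <- length(cancers)
  variants <- paste0(genes, "_hetero_anyPV")
  pen <- array(0, dim = c(R, K + 1L, 1L, 2L, 94L, 2L),
               dimnames = list(Cancer = cancers,
                               Gene = c(variants, "noncarrier"),
                               Race = "All_Races",
                               Sex = c("Female", "Male"),
                               Age = 1:94,
                               PenetType = c("Net", "Crude")))
  if (length(p_carrier) == 1L) p_carrier <- rep(p_carrier, K)
  for (r in seq_len(R)) {
    for (gi in seq_len(K + 1L)) {
      p <- if (gi == K + 1L) p_noncarrier else p_carrier[gi]
      pen[r, gi, 1L, "Female", , "Net"] <- p
      pen[r, gi, 1L, "Male", , "Net"] <- if (female_only) 0 else p
      pen[r, gi, 1L, "Female", , "Crude"] <- p * crude_ratio
      pen[r, gi, 1L, "Male", , "Crude"] <- if (female_only) 0 else p * crude_ratio
    }
  }
  if (length(freq) == 1L) freq <- rep(freq, K)
  af <- matrix(rep(freq, 3), K, 3,
               dimnames = list(Gene = genes,
                               Ancestry = c("AJ", "nonAJ", "Italian")))
  parameter_database(penetrance_table(pen), allele_frequency_table(af))
}

mdb_of <- function(db, cancers = NULL, genes = NULL) {
  if (is.null(cancers)) cancers <- dimnames(db$penetrance)$Cancer
  build_model_database(db, cancers = cancers, genes = genes)
}

# Minimal pedigree builder: fills schema defaults around the given columns.
ped_tbl <- function(ID, Sex, MotherID = NA, FatherID = NA, isProband = 0,
                    CurAge = 50, ...) {
  n <- length(ID)
  rec <- function(x) rep(x, length.out = n)
  df <- tibble::tibble(ID = rec(ID), Sex = rec(Sex),
                       MotherID = rec(MotherID), FatherID = rec(FatherID),
                       isProband = rec(isProband), CurAge = rec(CurAge))
  extra <- list(...)
  for (col in names(extra)) df[[col]] <- rep(extra[[col]], length.out = n)
  as_pedigree(df)
}

# Nuclear family: parents 1 (f), 2 (m), children 3..(2+n_children); child 3
# is the proband.
nuclear_ped <- function(n_children = 1, ..., proband = 3) {
  n <- 2 + n_children
  ped_tbl(ID = seq_len(n), Sex = c(0, 1, rbinom(n_children, 1, 0.5)),
          MotherID = c(NA, NA, rep(1, n_children)),
          FatherID = c(NA, NA, rep(2, n_children)),
          isProband = as.integer(seq_len(n) == proband),
          CurAge = c(75, 78, rep(45, n_children)), ...)
}

# Two sibling pairs intermarried across two families: a pedigree loop.
cross_sibling_ped <- function() {
  ped_tbl(
    ID = 1:10,
    Sex = c(0, 1, 1, 0, 0, 1, 0, 1, 1, 0),
    MotherID = c(NA, NA, 1, 1, NA, NA, 5, 5, 7, 4),
    FatherID = c(NA, NA, 2, 2, NA, NA, 6, 6, 3, 8),
    isProband = c(0, 0, 0, 0, 0, 0, 0, 0, 1, 0),
    CurAge = c(85, 88, 59, 55, 84, 86, 60, 62, 30, 28))
}

# First-cousin mating: the loop runs through the shared grandparents.
cousin_ped <- function() {
  ped_tbl(
    ID = 1:9,
    Sex = c(0, 1, 0, 1, 1, 0, 1, 0, 0),
    MotherID = c(NA, NA, 1, 1, NA, NA, 3, 6, 8),
    FatherID = c(NA, NA, 2, 2, NA, NA, 5, 4, 7),
    isProband = c(0, 0, 0, 0, 0, 0, 0, 0, 1),
    CurAge = c(90, 92, 65, 63, 66, 61, 40, 38, 15))
}

expect_posterior_sums_to_one <- function(post, tol = 1e-9) {
  for (pid in unique(post$proband)) {
    expect_equal(sum(post$probability[post$proband == pid]), 1,
                 tolerance = tol)
  }
}
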