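# Peeling engine against the exact enumeration oracle, plus structural
# posterior properties.

test_that("a singleton founder proband's posterior is the founder prior", {
  db <- const_db(genes = c("BRCA1", "BRCA2"), cancers = "Breast",
                 freq = c(0.01, 0.003))
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 2)
  ped <- ped_tbl(ID = 1, Sex = 0, isProband = 1, CurAge = NA_integer_,
                 isAffBC = 0L, AgeBC = NA_integer_)
  post <- peel(ped, mdb, sp)
  expect_equal(post$probability, founder_prior(sp, c(0.01, 0.003)),
               tolerance = 1e-12)
  post_bf <- brute_force_posterior(ped, mdb, sp)
  expect_equal(post_bf$probability, post$probability, tolerance = 1e-12)
})

test_that("peeling equals brute-force enumeration on random small families", {
  set.seed(401)
  n_checked <- 0
  for (rep in 1:30) {
    K <- sample(1:3, 1)
    m <- sample(seq_len(K), 1)
    db <- make_toy_database(genes = K, cancers = sample(1:2, 1),
                            races = "All_Races", seed = 500 + rep)
    gens <- sample(1:3, 1)
    sib <- if (gens == 3) sample(1:2, 1) else sample(1:3, 1)
    sim <- simulate_family(db, generations = gens, sibship = sib,
                           n_marry = 1, seed = 600 + rep)
    mdb <- mdb_of(db)
    sp <- enumerate_genotypes(mdb$gene_variants, m)
    if (length(sp$labels)^nrow(sim$pedigree) > 1e6) next
    p1 <- peel(sim$pedigree, mdb, sp)
    p2 <- brute_force_posterior(sim$pedigree, mdb, sp)
    expect_equal(p1$probability, p2$probability, tolerance = 1e-10)
    expect_posterior_sums_to_one(p1)
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("multiple probands in one pass match their single-proband runs", {
  db <- make_toy_database(genes = 2, cancers = 1, races = "All_Races",
                          seed = 21)
  sim <- simulate_family(db, generations = 2, sibship = 3, seed = 22)
  ped <- sim$pedigree
  ped$isProband <- as.integer(ped$ID %in% c(3L, 4L))
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 2)
  joint <- peel(ped, mdb, sp)
  for (pid in c(3L, 4L)) {
    solo <- ped
    solo$isProband <- as.integer(solo$ID == pid)
    ps <- peel(solo, mdb, sp)
    expect_equal(joint$probability[joint$proband == pid],
                 ps$probability, tolerance = 1e-12)
  }
})

test_that("relabeling individuals leaves the posterior unchanged", {
  db <- make_toy_database(genes = 2, cancers = 2, races = "All_Races",
                          seed = 31)
  sim <- simulate_family(db, generations = 3, sibship = 2, n_marry = 1,
                         seed = 32)
  ped <- sim$pedigree
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 2)
  base <- peel(ped, mdb, sp)
  # permute ids and row order
  set.seed(33)
  new_ids <- sample(100 + seq_len(nrow(ped)))
  relabel <- function(x) ifelse(is.na(x), NA_integer_,
                                new_ids[match(x, ped$ID)])
  ped2 <- ped
  ped2$MotherID <- relabel(ped$MotherID)
  ped2$FatherID <- relabel(ped$FatherID)
  ped2$ID <- new_ids
  ped2 <- ped2[sample(nrow(ped2)), ]
  perm <- peel(as_pedigree(ped2), mdb, sp)
  expect_equal(perm$probability, base$probability, tolerance = 1e-10)
})

test_that("the elimination order does not affect the marginal", {
  db <- make_toy_database(genes = 3, cancers = 1, races = "All_Races",
                          seed = 41)
  sim <- simulate_family(db, generations = 3, sibship = 2, n_marry = 1,
                         seed = 42)
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 2)
  base <- peel(sim$pedigree, mdb, sp)
  opts <- model_options()
  for (s in 1:3) {
    set.seed(s)
    opts$.elimination_order <- sample(paste0("u", seq_len(nrow(sim$pedigree))))
    alt <- peel(sim$pedigree, mdb, sp, opts)
    expect_equal(alt$probability, base$probability, tolerance = 1e-10)
  }
})

test_that("an affected first-degree relative raises the carrier probability", {
  db <- const_db(genes = "BRCA1", cancers = "Breast", p_carrier = 0.006,
                 p_noncarrier = 5e-4)
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 1)
  base <- nuclear_ped(1, isAffBC = 0L, AgeBC = NA_integer_)
  with_aff <- nuclear_ped(2, isAffBC = c(0L, 0L, 0L, 1L),
                          AgeBC = c(NA, NA, NA, 40L))
  p0 <- peel(base, mdb, sp)
  p1 <- peel(with_aff, mdb, sp)
  carrier0 <- 1 - p0$probability[p0$genotype == "noncarrier"]
  carrier1 <- 1 - p1$probability[p1$genotype == "noncarrier"]
  expect_gt(carrier1, carrier0)
})

test_that("identical twins share one genotype", {
  db <- const_db(genes = "BRCA1", cancers = "Breast", p_carrier = 0.006,
                 p_noncarrier = 5e-4)
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 1)
  ped <- nuclear_ped(2, isAffBC = c(0L, 0L, 0L, 1L),
                     AgeBC = c(NA, NA, NA, 40L))
  ped$Sex[3:4] <- 0L
  twin <- ped
  twin$Twins <- c(0L, 0L, 1L, 1L)
  # a carrier twin implies the proband twin carries: the affected twin's
  # evidence is stronger when genotypes are shared
  p_sib <- peel(ped, mdb, sp)
  p_twin <- peel(twin, mdb, sp)
  carrier_sib <- 1 - p_sib$probability[p_sib$genotype == "noncarrier"]
  carrier_twin <- 1 - p_twin$probability[p_twin$genotype == "noncarrier"]
  expect_gt(carrier_twin, carrier_sib)
  # twins agree with the oracle as well
  expect_equal(p_twin$probability,
               brute_force_posterior(twin, mdb, sp)$probability,
               tolerance = 1e-10)
})

test_that("the brute-force guard rejects oversized enumerations", {
  db <- const_db(genes = c("BRCA1", "BRCA2", "ATM"), cancers = "Breast")
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 3)
  sim <- simulate_family(db, generations = 3, sibship = 3, seed = 5)
  expect_error(brute_force_posterior(sim$pedigree, mdb, sp, guard = 1e4),
               class = "mendelrisk_size_error")
})
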