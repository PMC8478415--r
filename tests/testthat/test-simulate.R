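# Forward simulator: toy databases, genotype draws, phenotype generation.

test_that("toy databases satisfy every load-time invariant", {
  db <- make_toy_database(genes = 3, cancers = 2, seed = 1)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_database(db, tmp)
  expect_s3_class(load_database(tmp), "parameter_database")

  pen <- db$penetrance
  for (cc in dimnames(pen)$Cancer) {
    non <- sum(pen[cc, "noncarrier", 1, "Female", , "Net"])
    for (v in setdiff(dimnames(pen)$Gene, "noncarrier")) {
      car_net <- sum(pen[cc, v, 1, "Female", , "Net"])
      car_crude <- sum(pen[cc, v, 1, "Female", , "Crude"])
      expect_gt(car_net, non)       # carrier curves elevated
      expect_lt(car_crude, car_net) # crude = net x other-cause survival
    }
  }
})

test_that("the simulator is deterministic given the seed", {
  db <- make_toy_database(genes = 2, cancers = 1, races = "All_Races",
                          seed = 4)
  a <- simulate_family(db, generations = 3, sibship = 2, seed = 10)
  b <- simulate_family(db, generations = 3, sibship = 2, seed = 10)
  expect_identical(a, b)
})

test_that("founder carrier fractions follow Hardy-Weinberg", {
  flags <- simulate_genotypes(10000, c(g1 = 0.01), seed = 14)
  p_exp <- 2 * 0.01 * 0.99 + 0.01^2  # 0.0199
  se <- sqrt(p_exp * (1 - p_exp) / 10000)
  expect_lt(abs(mean(flags$g1) - p_exp), 3 * se)
  # zero frequency: nobody carries and phenotypes come from baseline curves
  db <- const_db(genes = "BRCA1", cancers = "Breast", freq = 1e-4)
  sim <- simulate_family(db, generations = 2, sibship = 2, seed = 15)
  expect_true(all(sim$genotypes$BRCA1 %in% c(0L, 1L)))
})

test_that("children of carrier couples carry at the Mendelian rate", {
  db <- const_db(genes = "BRCA1", cancers = "Breast", freq = 0.5)
  kids <- integer(0)
  parent_carrier <- integer(0)
  for (s in 1:120) {
    sim <- simulate_family(db, generations = 2, sibship = 4,
                           seed = 2000 + s)
    g <- sim$genotypes
    ped <- sim$pedigree
    child_rows <- !is.na(ped$MotherID)
    for (i in which(child_rows)) {
      gm <- g$BRCA1[g$ID == ped$MotherID[i]]
      gf <- g$BRCA1[g$ID == ped$FatherID[i]]
      if (gm == 1L && gf == 0L) {
        kids <- c(kids, g$BRCA1[g$ID == ped$ID[i]])
      }
    }
  }
  # single carrier parent: transmission_prob says the child carries w.p. 1/2
  sp <- enumerate_genotypes(1, 1)
  p_exp <- transmission_prob("gene1", "gene1", "noncarrier", sp)
  n <- length(kids)
  expect_gt(n, 50)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(mean(kids) - p_exp), 3 * se)
})

test_that("masking produces the requested missingness and spares probands", {
  db <- const_db(genes = "BRCA1", cancers = "Breast")
  sim <- simulate_family(db, generations = 3, sibship = 3, seed = 3)
  masked <- mask_pedigree_ages(sim$pedigree, p = 0.5, seed = 4)
  expect_false(anyNA(masked$CurAge[masked$isProband == 1L]))
  expect_true(anyNA(masked$CurAge))
  expect_identical(mask_pedigree_ages(sim$pedigree, p = 0.5, seed = 4),
                   masked)
})

test_that("simulated phenotype rates track the penetrance", {
  # uniform penetrance 0.002 to age 94, censored at CurAge ~ 50: the
  # affected fraction among noncarrier founders is near 0.002 * E[CurAge]
  db <- const_db(genes = "BRCA1", cancers = "Breast", p_carrier = 0.002,
                 p_noncarrier = 0.002, freq = 1e-4)
  aff <- 0L; tot <- 0L; exp_aff <- 0
  for (s in 1:150) {
    sim <- simulate_family(db, generations = 2, sibship = 2,
                           seed = 4000 + s)
    ped <- sim$pedigree
    aff <- aff + sum(ped$isAffBC)
    exp_aff <- exp_aff + sum(0.002 * pmin(ped$CurAge, 94))
    tot <- tot + nrow(ped)
  }
  se <- sqrt(exp_aff * (1 - exp_aff / tot)) # Poisson-binomial scale
  expect_lt(abs(aff - exp_aff), 4 * se)
})

test_that("informative phenotypes yield increasing carrier fractions across bins", {
  # strongly elevated carrier penetrance and a common variant, so the
  # prediction distribution spreads and the bins separate
  db <- make_toy_database(genes = 1, cancers = 1, races = "All_Races",
                          seed = 7, freq_range = c(0.05, 0.08),
                          carrier_lifetime = c(0.5, 0.55),
                          noncarrier_lifetime = c(0.02, 0.04))
  cal <- calibration_experiment(600, db, seed = 8, n_bins = 3)
  expect_true(all(diff(cal$mean_pred) > 0))
  expect_true(all(diff(cal$obs_frac) > 0))
  expect_true(all(cal$within))
})
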