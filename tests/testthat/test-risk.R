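# Future-risk projection from the genotype posterior.

point_mass_fit <- function(db, cur_age = 55, age_by = 5, net = FALSE) {
  # germline-positive proband forces a point-mass posterior on the carrier
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 1)
  ped <- ped_tbl(ID = 1, Sex = 0, isProband = 1, CurAge = cur_age,
                 isAffBC = 0L, AgeBC = NA_integer_)
  ped[[mdb$genes[1]]] <- 1L
  opts <- model_options(age_by = age_by, net = net)
  post <- peel(ped, mdb, sp, opts)
  list(post = post, risk = future_risk(post, ped, mdb, opts), mdb = mdb)
}

test_that("uniform crude penetrance reproduces the survival-conditioned sum", {
  db <- const_db(genes = "BRCA1", cancers = "Breast", p_carrier = 0.001,
                 p_noncarrier = 0.001, crude_ratio = 1)
  res <- point_mass_fit(db, cur_age = 55)
  expect_equal(res$post$probability[res$post$genotype == "BRCA1_hetero_anyPV"], 1)
  r60 <- res$risk$risk[res$risk$by_age == 60]
  expect_equal(r60, 5 * 0.001 / (1 - 55 * 0.001), tolerance = 1e-12)
})

test_that("the reporting grid runs from CurAge + age_by to the axis end", {
  db <- const_db(genes = "BRCA1", cancers = "Breast")
  res <- point_mass_fit(db, cur_age = 55, age_by = 5)
  expect_equal(res$risk$by_age, c(60L, 65L, 70L, 75L, 80L, 85L, 90L))
  res3 <- point_mass_fit(db, cur_age = 88, age_by = 3)
  expect_equal(res3$risk$by_age, c(91L, 94L))
})

test_that("risk is zero under a zero-penetrance genotype and monotone in age", {
  db0 <- const_db(genes = "BRCA1", cancers = "Ovarian", female_only = TRUE)
  mdb0 <- mdb_of(db0)
  sp <- enumerate_genotypes(mdb0$gene_variants, 1)
  # male proband: zero penetrance slice for every genotype
  pedm <- ped_tbl(ID = 1, Sex = 1, isProband = 1, CurAge = 50,
                  isAffOC = 0L, AgeOC = NA_integer_)
  post <- peel(pedm, mdb0, sp)
  risk <- future_risk(post, pedm, mdb0, model_options())
  expect_true(all(risk$risk == 0))

  db <- make_toy_database(genes = 2, cancers = 2, races = "All_Races",
                          seed = 77)
  sim <- simulate_family(db, generations = 2, sibship = 2, seed = 78)
  mdb <- mdb_of(db)
  post <- peel(sim$pedigree, mdb, enumerate_genotypes(mdb$gene_variants, 2))
  risk <- future_risk(post, sim$pedigree, mdb, model_options())
  for (cc in unique(risk$cancer)) {
    r <- risk$risk[risk$cancer == cc]
    expect_true(all(diff(r) >= -1e-12))
    expect_true(all(r >= 0 & r <= 1))
  }
})

test_that("a point-mass posterior reduces the mixture to the genotype curve", {
  db <- make_toy_database(genes = 1, cancers = 1, races = "All_Races",
                          seed = 55)
  res <- point_mass_fit(db, cur_age = 50)
  mdb <- res$mdb
  p <- mdb$penetrance[mdb$cancers[1], mdb$gene_variants[1], "All_Races",
                      "Female", , "Crude"]
  cum <- cumsum(p)
  expected <- (cum[seq(55, 90, by = 5)] - cum[50]) / (1 - cum[50])
  expect_equal(res$risk$risk, unname(expected), tolerance = 1e-12)
})

test_that("crude risk is below net risk when crude = net x survival", {
  db <- make_toy_database(genes = 1, cancers = 1, races = "All_Races",
                          seed = 56)
  crude <- point_mass_fit(db, cur_age = 50)$risk
  net <- point_mass_fit(db, cur_age = 50, net = TRUE)$risk
  expect_true(all(crude$risk < net$risk))
})

test_that("cancers the proband already had are omitted", {
  db <- const_db(genes = "BRCA1", cancers = c("Breast", "Ovarian"),
                 p_carrier = 0.002)
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 1)
  ped <- ped_tbl(ID = 1, Sex = 0, isProband = 1, CurAge = 50,
                 isAffBC = 1L, AgeBC = 45L, isAffOC = 0L,
                 AgeOC = NA_integer_)
  post <- peel(ped, mdb, sp)
  risk <- future_risk(post, ped, mdb, model_options())
  expect_setequal(unique(risk$cancer), "Ovarian")
})

test_that("a proband with unknown current age is skipped with a warning", {
  db <- const_db(genes = "BRCA1", cancers = "Breast")
  mdb <- mdb_of(db)
  sp <- enumerate_genotypes(mdb$gene_variants, 1)
  ped <- ped_tbl(ID = 1, Sex = 0, isProband = 1, CurAge = NA_integer_,
                 isAffBC = 0L, AgeBC = NA_integer_)
  post <- peel(ped, mdb, sp)
  expect_warning(risk <- future_risk(post, ped, mdb, model_options()),
                 "current age")
  expect_equal(nrow(risk), 0)
})
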