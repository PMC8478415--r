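# Pedigree validation, harmonization, loop detection, connectivity and
# pseudo-parents.

db3 <- make_toy_database(genes = c("BRCA1", "BRCA2", "ATM"),
                         cancers = c("Breast", "Ovarian"),
                         races = "All_Races", seed = 11)

test_that("heredity conflicts reset the child to the neutral category with a message", {
  ped <- nuclear_ped(2, isAffBC = 0L, AgeBC = NA_integer_)
  ped$Ancestry <- c("AJ", "AJ", "Italian", "AJ")
  ped$race <- c("White", "White", "Asian", "White")
  chk <- check_pedigree(ped, db3, cancers = "Breast")
  expect_match(paste(chk$report$messages, collapse = "\n"),
               "has been changed to nonAJ to meet heredity consistency")
  expect_match(paste(chk$report$messages, collapse = "\n"),
               "has been changed to All_Races to meet heredity consistency")
  expect_equal(chk$pedigree$Ancestry[chk$pedigree$ID == 3], "nonAJ")
  expect_equal(chk$pedigree$race[chk$pedigree$ID == 3], "All_Races")
  expect_equal(chk$report$changed_ids$ancestry_reset, 3L)
  expect_equal(chk$report$changed_ids$race_reset, 3L)
})

test_that("ancestry resets cascade to descendants", {
  # three generations; the middle generation conflicts, so the child's value
  # must be re-evaluated against the reset parent
  ped <- ped_tbl(ID = 1:5, Sex = c(0, 1, 0, 1, 0),
                 MotherID = c(NA, NA, 1, NA, 3),
                 FatherID = c(NA, NA, 2, NA, 4),
                 isProband = c(0, 0, 0, 0, 1),
                 CurAge = c(80, 82, 55, 57, 30),
                 isAffBC = 0L, AgeBC = NA_integer_)
  ped$Ancestry <- c("AJ", "AJ", "Italian", "Italian", "Italian")
  chk <- check_pedigree(ped, db3, cancers = "Breast")
  out <- chk$pedigree
  expect_equal(out$Ancestry[out$ID == 3], "nonAJ")
  # the grandchild's Italian now conflicts with {nonAJ, Italian}? it matches
  # the father, so it is retained
  expect_equal(out$Ancestry[out$ID == 5], "Italian")
})

test_that("a consistent pedigree is a fixed point and the check is idempotent", {
  ped <- nuclear_ped(2, isAffBC = c(0L, 0L, 1L, 0L),
                     AgeBC = c(NA, NA, 40L, NA), Ancestry = "nonAJ",
                     race = "All_Races")
  chk1 <- check_pedigree(ped, db3, cancers = "Breast")
  expect_length(chk1$report$changed_ids, 0)
  expect_equal(chk1$pedigree, ped)
  chk2 <- check_pedigree(chk1$pedigree, db3, cancers = "Breast")
  expect_equal(chk2$pedigree, chk1$pedigree)
  expect_length(chk2$report$changed_ids, 0)
})

test_that("the cross-sibling mating topology is rejected as a loop", {
  ped <- cross_sibling_ped()
  loops <- detect_loops(ped)
  expect_length(loops, 1)
  expect_true(all(c(3L, 4L, 7L, 8L) %in% loops[[1]]))
  expect_error(check_pedigree(ped, db3, cancers = "Breast"),
               class = "mendelrisk_loop_error")
})

test_that("first-cousin matings loop through the shared grandparents", {
  loops <- detect_loops(cousin_ped())
  expect_length(loops, 1)
  expect_true(all(c(3L, 4L, 7L, 8L) %in% loops[[1]]))
})

test_that("trees are loop-free", {
  expect_length(detect_loops(nuclear_ped(3)), 0)
  ped <- ped_tbl(ID = 1:7, Sex = c(0, 1, 0, 1, 1, 0, 0),
                 MotherID = c(NA, NA, 1, NA, 3, 3, NA),
                 FatherID = c(NA, NA, 2, NA, 4, 4, NA),
                 isProband = c(0, 0, 0, 0, 1, 0, 0))
  expect_length(detect_loops(ped), 0)
})

test_that("members disconnected from every proband are removed", {
  ped <- nuclear_ped(2, isAffBC = 0L, AgeBC = NA_integer_)
  lone <- ped_tbl(ID = 99, Sex = 1, CurAge = 70, isAffBC = 0L,
                  AgeBC = NA_integer_)
  ped2 <- as_pedigree(dplyr::bind_rows(ped, lone))
  rd <- remove_disconnected(ped2)
  expect_equal(rd$removed_ids, 99L)
  expect_equal(rd$pedigree$ID, ped$ID)
  # fixed point on a connected pedigree
  rd2 <- remove_disconnected(ped)
  expect_length(rd2$removed_ids, 0)
  expect_equal(rd2$pedigree, ped)
})

test_that("removing a childless in-law's family leaves the proband posterior unchanged", {
  # proband 3 with parents 1, 2; individual 10 is 3's spouse with no shared
  # children in the pedigree, and 11, 12 are the spouse's parents
  ped_full <- ped_tbl(ID = c(1, 2, 3, 10, 11, 12),
                      Sex = c(0, 1, 0, 1, 0, 1),
                      MotherID = c(NA, NA, 1, 11, NA, NA),
                      FatherID = c(NA, NA, 2, 12, NA, NA),
                      isProband = c(0, 0, 1, 0, 0, 0),
                      CurAge = c(75, 78, 45, 47, 70, 72),
                      isAffBC = c(1L, 0L, 0L, 0L, 1L, 0L),
                      AgeBC = c(50L, NA, NA, NA, 45L, NA))
  mdb <- mdb_of(const_db(genes = "BRCA1", cancers = "Breast",
                         p_carrier = 0.004, p_noncarrier = 5e-4))
  sp <- enumerate_genotypes(mdb$gene_variants, 1)
  post_full <- brute_force_posterior(ped_full, mdb, sp)
  rd <- remove_disconnected(ped_full)
  expect_setequal(rd$removed_ids, c(10L, 11L, 12L))
  post_kept <- brute_force_posterior(rd$pedigree, mdb, sp)
  expect_equal(post_kept$probability, post_full$probability,
               tolerance = 1e-12)
})

test_that("pseudo-parents complete single-parent links with matching priors", {
  ped <- ped_tbl(ID = 1:2, Sex = c(0, 0), MotherID = c(NA, 1),
                 FatherID = c(NA, NA), isProband = c(0, 1),
                 CurAge = c(70, 40), Ancestry = c("AJ", "AJ"))
  pp <- add_pseudo_parents(ped)
  expect_length(pp$added_ids, 1)
  added <- pp$pedigree[pp$pedigree$ID == pp$added_ids, ]
  expect_equal(added$Sex, 1L)              # missing side was the father
  expect_true(is.na(added$MotherID) && is.na(added$FatherID))
  expect_true(is.na(added$CurAge))
  expect_equal(added$Ancestry, "AJ")       # copied from the known parent
  expect_equal(pp$pedigree$FatherID[pp$pedigree$ID == 2], pp$added_ids)
  # both-parent individuals are untouched
  pp2 <- add_pseudo_parents(nuclear_ped(1))
  expect_length(pp2$added_ids, 0)
  # a chain of single-parent generations gets one pseudo-parent per level
  chain <- ped_tbl(ID = 1:3, Sex = c(0, 0, 0), MotherID = c(NA, 1, 2),
                   FatherID = NA, isProband = c(0, 0, 1),
                   CurAge = c(80, 55, 30))
  pp3 <- add_pseudo_parents(chain)
  expect_length(pp3$added_ids, 2)
  expect_length(unique(pp3$pedigree$ID), 5)
})

test_that("after the full check every non-founder has two parents and no loops remain", {
  ped <- ped_tbl(ID = 1:3, Sex = c(0, 0, 0), MotherID = c(NA, 1, 2),
                 FatherID = NA, isProband = c(0, 0, 1),
                 CurAge = c(80, 55, 30), isAffBC = 0L, AgeBC = NA_integer_)
  chk <- check_pedigree(ped, db3, cancers = "Breast")
  out <- chk$pedigree
  non_founder <- !is.na(out$MotherID) | !is.na(out$FatherID)
  expect_true(all(!is.na(out$MotherID[non_founder]) &
                    !is.na(out$FatherID[non_founder])))
  expect_length(detect_loops(out), 0)
})

test_that("unresolvable inconsistencies raise validation errors", {
  # male with a female-only cancer diagnosis
  dbf <- const_db(genes = "BRCA1", cancers = "Ovarian", female_only = TRUE)
  ped <- nuclear_ped(1, isAffOC = c(0L, 1L, 0L), AgeOC = c(NA, 60L, NA))
  expect_error(check_pedigree(ped, dbf, cancers = "Ovarian"),
               "incompatible", class = "mendelrisk_validation_error")
  # no proband
  ped2 <- nuclear_ped(1, proband = 0, isAffBC = 0L, AgeBC = NA_integer_)
  expect_error(check_pedigree(ped2, db3, cancers = "Breast"),
               "proband", class = "mendelrisk_validation_error")
  # diagnosis after the censoring age
  ped3 <- nuclear_ped(1, isAffBC = c(1L, 0L, 0L), AgeBC = c(80L, NA, NA))
  # mother's CurAge is 75 < AgeBC 80
  expect_error(check_pedigree(ped3, db3, cancers = "Breast"),
               "censoring age", class = "mendelrisk_validation_error")
  # inconsistent identical twins
  ped4 <- nuclear_ped(2, isAffBC = 0L, AgeBC = NA_integer_)
  ped4$Twins <- c(0L, 0L, 1L, 1L)
  ped4$Sex[3:4] <- c(0L, 1L)
  expect_error(check_pedigree(ped4, db3, cancers = "Breast"),
               "twin", class = "mendelrisk_validation_error")
})

test_that("ages beyond the penetrance axis are clamped with a warning", {
  ped <- nuclear_ped(1, isAffBC = 0L, AgeBC = NA_integer_)
  ped$CurAge[1] <- 101L
  expect_warning(chk <- check_pedigree(ped, db3, cancers = "Breast"),
                 "clamp")
  expect_equal(chk$pedigree$CurAge[1], 94L)
  expect_equal(chk$report$changed_ids$age_clamped, 1L)
})

test_that("germline result columns resolve to the default variant with a message", {
  ped <- nuclear_ped(1, isAffBC = 0L, AgeBC = NA_integer_)
  ped$BRCA1 <- c(NA_integer_, NA_integer_, 1L)
  chk <- check_pedigree(ped, db3, cancers = "Breast")
  expect_match(paste(chk$report$messages, collapse = "\n"),
               "BRCA1 are assumed to be for default variant BRCA1_hetero_anyPV")
})
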