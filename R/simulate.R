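# Synthetic data: toy parameter databases and a forward pedigree simulator
# with known genotype truth. The simulator draws exactly the generative
# model that the inference inverts — founder genotypes from Hardy-Weinberg
# priors, Mendelian transmission under the heterozygous-carrier model, and
# diagnosis ages from the genotype- and sex-specific net penetrances — so
# pushing simulated families through the engine provides calibration and
# parameter-recovery checks.

# Censoring-age model: generation means 75, 50, 25 (continuing downward by
# 25 per generation, floored), sd 8, clamped to [1, 94].
sim_cur_age <- function(gen) {
  mean_age <- max(75 - 25 * (gen), 20)
  as.integer(min(max(round(rnorm(1, mean_age, 8)), 1), MAX_AGE))
}

#' Build a toy parameter database
#'
#' Generates a fully synthetic database with smooth unimodal per-age net
#' penetrance curves (carrier curves elevated over the noncarrier
#' baseline), crude curves equal to net times a fixed other-cause survival
#' curve, and allele frequencies in \[1e-4, 1e-2\]. Female-only cancers
#' (Ovarian, Endometrial, Cervical) get identically zero male penetrance.
#' Deterministic given the seed.
#'
#' @param genes Gene names, or an integer count (names then come from a
#'   built-in panel).
#' @param cancers Cancer labels, or an integer count.
#' @param races Race axis levels (default all eight).
#' @param seed Integer seed.
#' @param carrier_lifetime,noncarrier_lifetime Ranges (length-2) for the
#'   female lifetime net penetrance of carriers and noncarriers.
#' @param freq_range Range for the nonAJ allele frequencies.
#' @return A `parameter_database`.
#' @export
#' @examples
#' db <- make_toy_database(genes = c("BRCA1", "BRCA2"), cancers = "Breast")
make_toy_database <- function(genes = 3, cancers = 2, races = RACES, seed = 1,
                              carrier_lifetime = c(0.25, 0.55),
                              noncarrier_lifetime = c(0.02, 0.08),
                              freq_range = c(1e-4, 1e-2)) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- PANEL_GENES[seq_len(genes)]
  }
  if (is.numeric(cancers) && length(cancers) == 1L) {
    cancers <- c("Breast", "Ovarian", "Colorectal", "Endometrial",
                 setdiff(unname(CANCER_TAGS), c("Breast", "Ovarian",
                                                "Colorectal", "Endometrial")))[seq_len(cancers)]
  }
  K <- length(genes)
  R <- length(cancers)
  variants <- variant_label(genes)
  ages <- seq_len(MAX_AGE)

  withr::with_seed(seed, {
    # other-cause mortality: Gompertz-like hazard, shared by all slices
    haz <- 5e-5 * exp(0.085 * ages)
    s_other <- exp(-cumsum(haz))

    pen <- array(0, dim = c(R, K + 1L, length(races), 2L, MAX_AGE, 2L),
                 dimnames = list(Cancer = cancers,
                                 Gene = c(variants, NONCARRIER),
                                 Race = races, Sex = SEXES, Age = ages,
                                 PenetType = PENET_TYPES))
    bump <- function(mu, sd, lifetime) {
      shape <- dnorm(ages, mu, sd)
      shape / sum(shape) * lifetime
    }
    for (r in seq_len(R)) {
      female_only <- cancers[r] %in% FEMALE_ONLY_CANCERS
      male_factor <- runif(1, 0.05, 0.5)  # shared per cancer, so carrier
                                          # elevation holds in both sexes
      for (gi in seq_len(K + 1L)) {
        noncar <- gi == K + 1L
        lifetime_f <- if (noncar) {
          runif(1, noncarrier_lifetime[1], noncarrier_lifetime[2])
        } else {
          runif(1, carrier_lifetime[1], carrier_lifetime[2])
        }
        mu <- runif(1, if (noncar) 60 else 45, if (noncar) 70 else 60)
        sd <- runif(1, 9, 14)
        net_f <- bump(mu, sd, lifetime_f)
        net_m <- if (female_only) rep(0, MAX_AGE) else net_f * male_factor
        for (race in races) {
          pen[r, gi, race, "Female", , "Net"] <- net_f
          pen[r, gi, race, "Male", , "Net"] <- net_m
          pen[r, gi, race, "Female", , "Crude"] <- net_f * s_other
          pen[r, gi, race, "Male", , "Crude"] <- net_m * s_other
        }
      }
    }

    f_non <- runif(K, freq_range[1], freq_range[2])
    af <- cbind(AJ = pmin(f_non * 2, 0.5), nonAJ = f_non,
                Italian = f_non * 0.8)
    dimnames(af) <- list(Gene = genes, Ancestry = ANCESTRIES)

    parameter_database(penetrance_table(pen), allele_frequency_table(af))
  })
}

#' Draw founder genotypes under Hardy-Weinberg priors
#'
#' @param n Number of founders.
#' @param freqs Named vector of allele frequencies, one per gene.
#' @param seed Optional seed.
#' @return An `n x K` tibble of 0/1 carrier flags.
#' @export
simulate_genotypes <- function(n, freqs, seed = NULL) {
  draw <- function() {
    carrier <- 2 * freqs * (1 - freqs) + freqs^2
    flags <- vapply(carrier, function(p) rbinom(n, 1L, p), integer(n))
    flags <- matrix(flags, nrow = n,
                    dimnames = list(NULL, names(freqs)))
    as_tibble(flags)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

sim_child_flags <- function(mother, father) {
  # heterozygous-carrier model: each carrier parent transmits w.p. 1/2
  from_m <- rbinom(length(mother), 1L, mother * 0.5)
  from_f <- rbinom(length(father), 1L, father * 0.5)
  as.integer(from_m | from_f)
}

sim_phenotype <- function(mdb, flags, sex, cur_age, opts) {
  aff <- integer(length(mdb$cancers))
  dia <- rep(NA_integer_, length(mdb$cancers))
  for (r in seq_along(mdb$cancers)) {
    p <- genotype_curve(mdb, flags, mdb$cancers[r], NA, sex, "Net", opts)
    t_onset <- sample.int(MAX_AGE + 1L, 1L, prob = c(p, max(1 - sum(p), 0)))
    if (t_onset <= cur_age) {
      aff[r] <- 1L
      dia[r] <- t_onset
    }
  }
  list(aff = aff, diag = dia)
}

#' Simulate a pedigree with known genotypes
#'
#' Builds a regular multi-generation family (a founder couple, `sibship`
#' children per couple, with `n_marry` children per sibship marrying
#' into new founder spouses down to `generations` levels), draws genotypes
#' by Hardy-Weinberg priors and Mendelian transmission, and draws each
#' member's cancer history from the genotype-specific net penetrances
#' censored at a generation-dependent current age. The proband is the first
#' member of the youngest generation. `generations = 1` gives a single
#' founder proband.
#'
#' @param database A `parameter_database`.
#' @param generations Number of generations (>= 1).
#' @param sibship Children per couple.
#' @param n_marry How many children per sibship marry and reproduce
#'   (default: all, capped at the sibship size); only used when
#'   `generations > 2`.
#' @param cancers,genes Model subset passed to [build_model_database()].
#' @param ancestry Founder ancestry label.
#' @param seed Optional seed.
#' @return A list with `pedigree` (an observable pedigree tibble, genotypes
#'   not included) and `genotypes` (tibble of true carrier flags per ID).
#' @export
simulate_family <- function(database, generations = 2, sibship = 2,
                            n_marry = NULL, cancers = NULL, genes = NULL,
                            ancestry = "nonAJ", seed = NULL) {
  stopifnot(generations >= 1, sibship >= 1)
  if (is.null(cancers)) cancers <- unique(dimnames(database$penetrance)$Cancer)
  mdb <- build_model_database(database, cancers = cancers, genes = genes)
  if (is.null(n_marry)) n_marry <- sibship
  n_marry <- min(n_marry, sibship)
  opts <- model_options()
  freqs <- ancestry_freqs(mdb, ancestry)
  K <- length(freqs)

  build <- function() {
    rows <- list()
    geno <- list()
    next_id <- 0L
    new_person <- function(sex, gen, mother = NA_integer_,
                           father = NA_integer_, flags = NULL) {
      next_id <<- next_id + 1L
      if (is.null(flags)) {
        carrier <- 2 * freqs * (1 - freqs) + freqs^2
        flags <- as.integer(rbinom(K, 1L, carrier))
      }
      cur <- sim_cur_age(gen)
      ph <- sim_phenotype(mdb, flags, sex, cur, opts)
      rec <- list(ID = next_id, MotherID = mother, FatherID = father,
                  Sex = sex, isProband = 0L, CurAge = cur, isDead = 0L,
                  race = NA_character_, Ancestry = ancestry, Twins = 0L)
      tags <- names(mdb$cancer_tags)[match(mdb$cancers, mdb$cancer_tags)]
      for (r in seq_along(mdb$cancers)) {
        rec[[aff_col(tags[r])]] <- ph$aff[r]
        rec[[age_col(tags[r])]] <- ph$diag[r]
      }
      rows[[next_id]] <<- rec
      geno[[next_id]] <<- flags
      next_id
    }

    if (generations == 1L) {
      pid <- new_person(sex = rbinom(1, 1, 0.5), gen = 0L)
      rows[[pid]]$isProband <- 1L
    } else {
      mother0 <- new_person(0L, 0L)
      father0 <- new_person(1L, 0L)
      frontier <- list(list(mother = mother0, father = father0, gen = 0L))
      youngest <- integer(0)
      for (gen in seq_len(generations - 1L)) {
        next_frontier <- list()
        youngest <- integer(0)
        for (cp in frontier) {
          kids <- integer(sibship)
          for (s in seq_len(sibship)) {
            flags <- sim_child_flags(geno[[cp$mother]], geno[[cp$father]])
            kids[s] <- new_person(rbinom(1, 1, 0.5), gen,
                                  mother = cp$mother, father = cp$father,
                                  flags = flags)
          }
          youngest <- c(youngest, kids)
          if (gen < generations - 1L) {
            for (s in seq_len(n_marry)) {
              child <- kids[s]
              spouse_sex <- 1L - rows[[child]]$Sex
              spouse <- new_person(spouse_sex, gen)
              couple <- if (spouse_sex == 0L) {
                list(mother = spouse, father = child)
              } else {
                list(mother = child, father = spouse)
              }
              couple$gen <- gen
              next_frontier[[length(next_frontier) + 1L]] <- couple
            }
          }
        }
        frontier <- next_frontier
      }
      rows[[youngest[1L]]]$isProband <- 1L
    }

    ped <- as_pedigree(bind_rows(lapply(rows, as_tibble)))
    gmat <- do.call(rbind, geno)
    colnames(gmat) <- mdb$genes
    genotypes <- as_tibble(cbind(tibble(ID = seq_len(nrow(gmat))),
                                 as_tibble(gmat)))
    list(pedigree = ped, genotypes = genotypes)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Mask ages at random to create missing data
#'
#' The missingness mechanism used for imputation testing: each censoring
#' age and each diagnosis age is independently set to missing with
#' probability `p` (probands' censoring ages are never masked, since the
#' risk grid needs them).
#'
#' @param ped A pedigree tibble.
#' @param p Masking probability (default 0.2).
#' @param seed Optional seed.
#' @return The pedigree with masked ages.
#' @export
mask_pedigree_ages <- function(ped, p = 0.2, seed = NULL) {
  mask <- function() {
    maskable <- ped$isProband != 1L
    hit <- runif(nrow(ped)) < p & maskable
    ped$CurAge[hit] <- NA_integer_
    for (tag in pedigree_cancers(ped)) {
      col <- age_col(tag)
      hit <- runif(nrow(ped)) < p & !is.na(ped[[col]])
      ped[[col]][hit] <- NA_integer_
    }
    ped
  }
  if (is.null(seed)) mask() else withr::with_seed(seed, mask())
}

#' Calibration experiment: simulate, predict, and bin
#'
#' Simulates `n_families` pedigrees with known genotypes, runs the full
#' engine on each observable pedigree, bins the probands into equal-size
#' bins of predicted total carrier probability, and compares each bin's
#' observed true-carrier fraction with a 99% binomial interval around the
#' bin's mean prediction. A correctly implemented engine is calibrated by
#' construction, since the simulator draws from the model the inference
#' inverts.
#'
#' @param n_families Number of simulated families.
#' @param database A `parameter_database`.
#' @param options A [model_options()] list used for the engine runs.
#' @param seed Integer seed (drives both simulation and engine).
#' @param n_bins Number of prediction bins (default 10).
#' @param generations,sibship,cancers,genes Passed to [simulate_family()].
#' @return A tibble with one row per bin: `bin`, `n`, `mean_pred`,
#'   `n_carriers`, `obs_frac`, `lower`, `upper` (99% binomial bounds at the
#'   mean prediction) and `within`.
#' @export
calibration_experiment <- function(n_families, database,
                                   options = model_options(iterations = 1),
                                   seed = 1, n_bins = 10,
                                   generations = 2, sibship = 3,
                                   cancers = NULL, genes = NULL) {
  fam_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1L, n_families))
  pred <- truth <- numeric(n_families)
  for (j in seq_len(n_families)) {
    sim <- simulate_family(database, generations = generations,
                           sibship = sibship, cancers = cancers,
                           genes = genes, seed = fam_seeds[j])
    fit <- run_model(sim$pedigree, cancers = cancers, genes = genes,
                     database = database, options = options)
    nc <- fit$posterior[fit$posterior$genotype == NONCARRIER, ]
    pred[j] <- 1 - nc$estimate[1]
    pid <- nc$proband[1]
    gl <- sim$genotypes[sim$genotypes$ID == pid, -1, drop = FALSE]
    truth[j] <- as.integer(any(gl == 1L))
  }
  df <- tibble(pred = pred, truth = truth,
               bin = ntile(pred, n_bins))
  df %>%
    group_by(.data$bin) %>%
    summarise(n = n(),
              mean_pred = mean(.data$pred),
              n_carriers = sum(.data$truth),
              obs_frac = mean(.data$truth),
              .groups = "drop") %>%
    mutate(lower = qbinom(0.005, .data$n, .data$mean_pred) / .data$n,
           upper = qbinom(0.995, .data$n, .data$mean_pred) / .data$n,
           within = .data$obs_frac >= .data$lower &
                    .data$obs_frac <= .data$upper)
}
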