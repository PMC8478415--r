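# Phenotype likelihoods P(H_i | G_i, sex_i).
#
# For each cancer the likelihood follows the standard two-case censoring
# form, using NET penetrances (competing mortality is not part of the
# observed family history):
#   unaffected: 1 - sum_{s=1..C} P(T = s | G, sex)   (survival to the
#               censoring age C)
#   affected:   P(T = t_obs | G, sex)                 (density at the
#               observed diagnosis age)
# Individuals whose censoring age was not observed contribute no survival
# information (factor 1) for their unaffected cancers, so a relative with no
# phenotype data and unknown ages is exactly uninformative. Germline test
# results enter as a sensitivity/specificity factor per tested gene (perfect
# test by default), tumor-marker results through a pluggable per-marker
# factor (uninformative by default), and prophylactic surgeries scale the
# per-age penetrance of their target cancer from the intervention age onward.

# For a multi-carrier genotype the per-cancer penetrance is taken from the
# carried variant with the largest cumulative net penetrance for that cancer
# and sex (dominant-gene rule; ties broken by gene order).
assign_variant <- function(mdb, flags, cancer, race, sex) {
  carried <- mdb$gene_variants[flags == 1L]
  if (!length(carried)) return(NONCARRIER)
  if (length(carried) == 1L) return(carried)
  cums <- vapply(carried, function(v) {
    sum(mdb$penetrance[cancer, v, resolve_race(mdb, race), resolve_sex(sex), , "Net"])
  }, numeric(1))
  carried[which.max(cums)]
}

# Penetrance curve for a genotype, with risk-modifier adjustment. riskmod /
# inter_age come from the individual's columns; factors and the surgery ->
# cancer map from the options.
genotype_curve <- function(mdb, flags, cancer, race, sex, type, opts,
                           riskmod = character(0), inter_age = integer(0)) {
  v <- assign_variant(mdb, flags, cancer, race, sex)
  p <- mdb$penetrance[cancer, v, resolve_race(mdb, race), resolve_sex(sex), , type]
  if (length(riskmod)) {
    for (j in seq_along(riskmod)) {
      surg <- riskmod[j]
      target <- opts$riskmod_map[surg]
      if (is.na(target) || target != cancer) next
      a <- inter_age[j]
      if (is.na(a)) next
      fac <- opts$riskmod_factors[surg]
      if (is.na(fac)) fac <- 1
      a <- max(1L, min(as.integer(a), MAX_AGE))
      p[a:MAX_AGE] <- p[a:MAX_AGE] * fac
    }
  }
  unname(p)
}

# Log-likelihood of one individual's observed history for one genotype.
# `ind` is the internal per-individual record built by fam_internal().
loglik_individual <- function(ind, flags, mdb, opts, curve_cache = NULL) {
  ll <- 0
  for (r in seq_along(mdb$cancers)) {
    cancer <- mdb$cancers[r]
    aff <- ind$aff[r]
    if (is.na(aff)) next
    key <- NULL
    if (!is.null(curve_cache) && !length(ind$riskmod)) {
      v <- assign_variant(mdb, flags, cancer, ind$race, ind$sex)
      key <- paste(cancer, v, resolve_race(mdb, ind$race), ind$sex, sep = "\r")
      p <- get0(key, envir = curve_cache, ifnotfound = NULL)
      if (is.null(p)) {
        p <- genotype_curve(mdb, flags, cancer, ind$race, ind$sex, "Net", opts)
        assign(key, p, envir = curve_cache)
      }
    } else {
      p <- genotype_curve(mdb, flags, cancer, ind$race, ind$sex, "Net", opts,
                          ind$riskmod, ind$inter_age)
    }
    if (aff == 1L) {
      t_obs <- ind$diag_age[r]
      if (!is.na(t_obs)) {
        ll <- ll + log(p[min(max(t_obs, 1L), MAX_AGE)])
      } else if (!is.na(ind$cur_age)) {
        # affected at an unknown age: probability of onset by the censoring age
        ll <- ll + log(sum(p[seq_len(min(ind$cur_age, MAX_AGE))]))
      }
    } else if (ind$cur_age_known && !is.na(ind$cur_age)) {
      surv <- 1 - sum(p[seq_len(min(ind$cur_age, MAX_AGE))])
      ll <- ll + log(max(surv, 0))
    }
  }
  # germline panel results: perfect test by default
  if (length(ind$germline)) {
    sens <- opts$germline_sensitivity
    spec <- opts$germline_specificity
    for (g in names(ind$germline)) {
      res <- ind$germline[[g]]
      if (is.na(res)) next
      carrier <- flags[match(g, mdb$genes)] == 1L
      pr <- if (carrier) {
        if (res == 1L) sens else 1 - sens
      } else {
        if (res == 1L) 1 - spec else spec
      }
      ll <- ll + log(pr)
    }
  }
  if (!is.null(opts$marker_likelihood) && length(ind$markers)) {
    for (mk in names(ind$markers)) {
      res <- ind$markers[[mk]]
      if (is.na(res)) next
      ll <- ll + log(opts$marker_likelihood(mk, res, flags))
    }
  }
  ll
}

#' Phenotype likelihood of one individual for one genotype
#'
#' Computes `P(H_i | G_i, sex_i)`: the product over the model cancers of the
#' censored-history likelihood (net penetrances), times the germline-test
#' and marker factors.
#'
#' @param ind One pedigree row (a one-row data frame in the pedigree
#'   schema).
#' @param genotype Genotype as a carrier-flag vector over the model genes or
#'   a genotype label (`"noncarrier"` or dot-joined variant labels).
#' @param mdb A `model_database`.
#' @param options A [model_options()] list.
#' @return A single probability (possibly 0).
#' @export
phenotype_likelihood <- function(ind, genotype, mdb, options = model_options()) {
  stopifnot(nrow(ind) == 1L)
  flags <- resolve_flags(mdb, genotype)
  rec <- individual_record(ind, mdb)
  exp(loglik_individual(rec, flags, mdb, options))
}

resolve_flags <- function(mdb, genotype) {
  K <- length(mdb$gene_variants)
  if (is.numeric(genotype)) {
    stopifnot(length(genotype) == K)
    return(as.integer(genotype))
  }
  flags <- integer(K)
  if (identical(genotype, NONCARRIER)) return(flags)
  parts <- strsplit(genotype, ".", fixed = TRUE)[[1]]
  idx <- match(parts, mdb$gene_variants)
  idx[is.na(idx)] <- match(parts[is.na(idx)], mdb$genes)
  if (anyNA(idx)) {
    mr_error(paste0("cannot resolve genotype label '", genotype, "'"),
             "mendelrisk_lookup_error")
  }
  flags[idx] <- 1L
  flags
}

# Internal per-individual record used by the likelihood and the engines.
individual_record <- function(row, mdb) {
  tags <- names(mdb$cancer_tags)[match(mdb$cancers, mdb$cancer_tags)]
  aff <- rep(NA_integer_, length(mdb$cancers))
  dia <- rep(NA_integer_, length(mdb$cancers))
  for (r in seq_along(mdb$cancers)) {
    tg <- tags[r]
    if (!is.na(tg) && aff_col(tg) %in% names(row)) {
      aff[r] <- row[[aff_col(tg)]]
      dia[r] <- row[[age_col(tg)]]
    }
  }
  germ <- list()
  for (g in mdb$genes) {
    if (g %in% names(row)) germ[[g]] <- as.integer(row[[g]])
  }
  markers <- list()
  for (mk in intersect(MARKERS, names(row))) {
    markers[[mk]] <- as.integer(row[[mk]])
  }
  cur_age_known <- if (".curAgeKnown" %in% names(row)) {
    isTRUE(row$.curAgeKnown)
  } else {
    !is.na(row$CurAge)
  }
  list(
    id = row$ID,
    sex = row$Sex,
    race = row$race,
    ancestry = row$Ancestry,
    cur_age = row$CurAge,
    cur_age_known = cur_age_known,
    aff = aff,
    diag_age = dia,
    riskmod = if ("riskmod" %in% names(row)) row$riskmod[[1]] else character(0),
    inter_age = if ("InterAge" %in% names(row)) row$InterAge[[1]] else integer(0),
    germline = germ,
    markers = markers
  )
}

# Likelihood matrix: rows = pedigree rows, columns = genotype states.
likelihood_matrix <- function(ped, space, mdb, opts) {
  S <- space_size(space)
  n <- nrow(ped)
  L <- matrix(0, n, S)
  cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    rec <- individual_record(ped[i, ], mdb)
    for (s in seq_len(S)) {
      L[i, s] <- exp(loglik_individual(rec, space$flags[s, ], mdb, opts, cache))
    }
  }
  rownames(L) <- as.character(ped$ID)
  L
}
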