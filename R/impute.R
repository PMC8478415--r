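# Multiple imputation of missing current and diagnosis ages, and min /
# mean / max aggregation of per-imputation results.
#
# Missing current ages are sampled from the current ages of the relatives:
# the mean of the same-generation known ages plus Normal(0, 10) noise,
# clamped to [1, 94] and to sit at least 15 years above every known child
# and 15 years below every known parent. When a generation has no known
# ages, known ages elsewhere are shifted by 25 years per generation; when no
# age is known anywhere a fallback prior of 75 minus 25 per generation is
# used (with a warning). Missing diagnosis ages of affected members are
# sampled from the model-averaged net penetrance under the founder priors,
# truncated at the individual's censoring age. All draws are reproducible
# from the seed; per-imputation substreams are derived deterministically
# from it, so sequential and parallel execution agree bit-for-bit.

GEN_GAP <- 25L    # years per generation used by the fallback rules
PARENT_GAP <- 15L # minimum parent-child age separation
AGE_SD <- 10      # noise around the relative-based age estimate

#' Multiply impute missing ages in a pedigree
#'
#' @param ped A checked pedigree tibble.
#' @param mdb A `model_database` (supplies penetrances and allele
#'   frequencies for the diagnosis-age distribution).
#' @param iterations Number of imputed pedigrees to draw (default 20). When
#'   nothing is missing a single pedigree identical to the input is
#'   returned, regardless of `iterations`.
#' @param seed Integer seed; the same seed reproduces the same list.
#' @return A list of completed pedigrees. Imputed pedigrees carry a hidden
#'   `.curAgeKnown` column marking which censoring ages were observed:
#'   unaffected members with originally unknown ages stay uninformative in
#'   the likelihood.
#' @export
impute_ages <- function(ped, mdb, iterations = 20, seed = NULL) {
  stopifnot(iterations >= 1)
  tags <- intersect(pedigree_cancers(ped), names(mdb$cancer_tags))
  missing_cur <- is.na(ped$CurAge)
  missing_dia <- lapply(tags, function(tag) {
    which(!is.na(ped[[aff_col(tag)]]) & ped[[aff_col(tag)]] == 1L &
            is.na(ped[[age_col(tag)]]))
  })
  names(missing_dia) <- tags
  if (!any(missing_cur) && !any(lengths(missing_dia) > 0)) {
    return(list(ped))
  }

  draw_one <- function() impute_once(ped, mdb, tags, missing_cur, missing_dia)
  if (is.null(seed)) {
    return(lapply(seq_len(iterations), function(j) draw_one()))
  }
  iter_seeds <- withr::with_seed(seed,
                                 sample.int(.Machine$integer.max - 1L, iterations))
  lapply(iter_seeds, function(s) withr::with_seed(s, draw_one()))
}

impute_once <- function(ped, mdb, tags, missing_cur, missing_dia) {
  out <- ped
  out$.curAgeKnown <- !missing_cur
  depth <- generation_depth(ped)
  known_age <- ped$CurAge
  mo <- match(ped$MotherID, ped$ID)
  fa <- match(ped$FatherID, ped$ID)

  if (any(missing_cur)) {
    any_known <- any(!is.na(known_age))
    if (!any_known) {
      warning("no current age is known anywhere in the pedigree; ",
              "using the generation-based fallback prior", call. = FALSE)
    }
    ord <- order(depth, ped$ID)
    for (i in ord[missing_cur[ord]]) {
      same_gen <- which(depth == depth[i] & !is.na(known_age))
      base <- if (length(same_gen)) {
        mean(known_age[same_gen])
      } else if (any_known) {
        k <- which(!is.na(known_age))
        mean(known_age[k] - GEN_GAP * (depth[i] - depth[k]))
      } else {
        75 - GEN_GAP * depth[i]
      }
      draw <- round(base + rnorm(1, 0, AGE_SD))
      children <- which((!is.na(mo) & mo == i) | (!is.na(fa) & fa == i))
      kid_ages <- known_age[children]
      kid_ages <- kid_ages[!is.na(kid_ages)]
      par_ages <- known_age[c(mo[i], fa[i])]
      par_ages <- par_ages[!is.na(par_ages)]
      lo <- max(1, if (length(kid_ages)) max(kid_ages) + PARENT_GAP else 1)
      hi <- min(MAX_AGE, if (length(par_ages)) min(par_ages) - PARENT_GAP else MAX_AGE)
      if (lo > hi) lo <- hi <- round((lo + hi) / 2)
      out$CurAge[i] <- as.integer(min(max(draw, lo, 1), hi, MAX_AGE))
    }
  }

  for (tag in tags) {
    rows <- missing_dia[[tag]]
    if (!length(rows)) next
    cancer <- unname(mdb$cancer_tags[tag])
    for (i in rows) {
      C <- min(out$CurAge[i], MAX_AGE)
      if (is.na(C)) C <- MAX_AGE
      pbar <- averaged_penetrance(mdb, cancer, ped$Sex[i], ped$race[i],
                                  ped$Ancestry[i])
      w <- pbar[seq_len(C)]
      if (sum(w) <= 0) {
        warning("model-averaged penetrance is zero below the censoring age; ",
                "sampling the diagnosis age uniformly", call. = FALSE)
        w <- rep(1, C)
      }
      out[[age_col(tag)]][i] <- sample.int(C, 1L, prob = w)
    }
  }
  out
}

# Net penetrance curve averaged over genotype classes (noncarrier plus each
# single-carrier state) weighted by HWE founder priors: the genotype is
# unknown at imputation time.
averaged_penetrance <- function(mdb, cancer, sex, race, ancestry) {
  freqs <- ancestry_freqs(mdb, ancestry)
  carrier <- 2 * freqs * (1 - freqs) + freqs^2
  w_non <- prod(1 - carrier)
  w_single <- vapply(seq_along(carrier), function(k) {
    carrier[k] * prod(1 - carrier[-k])
  }, numeric(1))
  w <- c(w_non, w_single)
  w <- w / sum(w)
  curves <- rbind(
    mdb$penetrance[cancer, NONCARRIER, resolve_race(mdb, race),
                   resolve_sex(sex), , "Net"],
    t(vapply(mdb$gene_variants, function(v) {
      mdb$penetrance[cancer, v, resolve_race(mdb, race), resolve_sex(sex), , "Net"]
    }, numeric(MAX_AGE))))
  as.vector(w %*% curves)
}

#' Aggregate per-imputation results into estimate / lower / upper
#'
#' Element-wise across a list of congruent result tables: `estimate` is the
#' mean over imputations, `lower` the minimum and `upper` the maximum. With
#' a single table the three coincide.
#'
#' @param results A list of tibbles sharing the same key rows (in the same
#'   order) and one value column.
#' @param value Name of the value column; defaults to the single
#'   non-key numeric column (`probability` or `risk`).
#' @return A tibble with the key columns plus `estimate`, `lower`, `upper`.
#' @export
aggregate_imputations <- function(results, value = NULL) {
  stopifnot(is.list(results), length(results) >= 1)
  first <- results[[1]]
  if (is.null(value)) {
    value <- intersect(c("probability", "risk"), names(first))[1]
    if (is.na(value)) {
      mr_error("cannot find a value column ('probability' or 'risk')",
               "mendelrisk_validation_error")
    }
  }
  keys <- setdiff(names(first), value)
  key_tab <- first[keys]
  for (r in results[-1]) {
    if (!identical(names(r), names(first)) || nrow(r) != nrow(first) ||
        !identical(r[keys], key_tab)) {
      mr_error("imputation results are not congruent (keys differ)",
               "mendelrisk_validation_error")
    }
  }
  vals <- vapply(results, function(r) r[[value]], numeric(nrow(first)))
  vals <- matrix(vals, nrow = nrow(first))
  out <- key_tab
  out$estimate <- rowMeans(vals)
  out$lower <- apply(vals, 1, min)
  out$upper <- apply(vals, 1, max)
  as_tibble(out)
}
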