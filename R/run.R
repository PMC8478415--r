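# Top-level orchestration: check -> build -> impute -> peel -> risk ->
# aggregate.

#' Run-time options for the risk engine
#'
#' @param max_mut Paring parameter: maximum number of simultaneous
#'   mutations per individual. `NULL` (the default) re-defaults to 2; values
#'   above the gene count are clamped.
#' @param iterations Number of age imputations when ages are missing
#'   (default 20).
#' @param parallel Evaluate imputation passes on multiple cores when
#'   available (default `TRUE`). Results are bit-identical to sequential
#'   execution for the same seed: all random draws happen up front in
#'   [impute_ages()] from seed-derived substreams.
#' @param net Use net instead of crude penetrances for future risk
#'   (default `FALSE`).
#' @param age_by Age interval of the future-risk grid (default 5 years).
#' @param seed Integer seed driving the imputation draws.
#' @param germline_sensitivity,germline_specificity Sensitivity and
#'   specificity of germline test results (default 1: a perfect test, so a
#'   positive result zeroes non-carrier genotypes for that gene and a
#'   negative zeroes carriers).
#' @param riskmod_factors Named per-surgery hazard factors applied to the
#'   target cancer's per-age penetrance from the intervention age onward
#'   (defaults are neutral: factor 1).
#' @param riskmod_map Named map surgery -> target cancer.
#' @param marker_likelihood Optional function
#'   `(marker, result, carrier_flags) -> probability` multiplying the
#'   likelihood for tumor-marker results; `NULL` (default) treats markers
#'   as uninformative.
#' @return A list with class `model_options`.
#' @export
model_options <- function(max_mut = NULL, iterations = 20, parallel = TRUE,
                          net = FALSE, age_by = 5, seed = NULL,
                          germline_sensitivity = 1, germline_specificity = 1,
                          riskmod_factors = c(mastectomy = 1, oophorectomy = 1,
                                              hysterectomy = 1),
                          riskmod_map = c(mastectomy = "Breast",
                                          oophorectomy = "Ovarian",
                                          hysterectomy = "Endometrial"),
                          marker_likelihood = NULL) {
  if (!is.null(max_mut)) {
    max_mut <- as.integer(max_mut)
    stopifnot(max_mut >= 1L)
  }
  stopifnot(iterations >= 1, age_by >= 1,
            germline_sensitivity >= 0, germline_sensitivity <= 1,
            germline_specificity >= 0, germline_specificity <= 1)
  structure(
    list(max_mut = max_mut, iterations = as.integer(iterations),
         parallel = isTRUE(parallel), net = isTRUE(net),
         age_by = as.integer(age_by), seed = seed,
         germline_sensitivity = germline_sensitivity,
         germline_specificity = germline_specificity,
         riskmod_factors = riskmod_factors, riskmod_map = riskmod_map,
         marker_likelihood = marker_likelihood),
    class = "model_options")
}

#' Posterior carrier probabilities and future cancer risks for a family
#'
#' The main entry point: validates and repairs the pedigree, subsets the
#' parameter database to the requested cancers and genes, imputes missing
#' ages, runs pedigree peeling over the pared genotype space for every
#' proband, projects future cancer risks, and aggregates the per-imputation
#' results into estimate / lower / upper tables.
#'
#' @param pedigree A pedigree tibble (see [read_pedigree()]).
#' @param cancers,genes Model specification; `NULL` defaults to all database
#'   genes and the pedigree's cancers. Ignored when `preset` is given.
#' @param database A `parameter_database`; defaults to the bundled
#'   [toy_database()] (synthetic parameters — supply a curated database for
#'   real counseling).
#' @param preset Optional single-syndrome preset name (see
#'   [preset_model()]); running a preset is exactly equivalent to passing
#'   its cancers and genes explicitly.
#' @param options A [model_options()] list.
#' @return An object of class `mendel_risk`: a list with tibbles
#'   `posterior` (`proband`, `genotype`, `estimate`, `lower`, `upper`) and
#'   `future_risk` (`proband`, `cancer`, `by_age`, `estimate`, `lower`,
#'   `upper`), the `check_report`, and the run metadata. With no missing
#'   ages, `lower = estimate = upper`.
#' @seealso [tidy.mendel_risk()], [autoplot.mendel_risk()],
#'   [write_result()]
#' @export
#' @examples
#' ped <- read_pedigree(system.file("extdata", "family_breast_ovarian.csv",
#'                                  package = "mendelrisk"))
#' fit <- run_model(ped, cancers = c("Breast", "Ovarian"),
#'                  options = model_options(seed = 1))
#' tidy(fit)
run_model <- function(pedigree, cancers = NULL, genes = NULL, database = NULL,
                      preset = NULL, options = model_options()) {
  stopifnot(inherits(options, "model_options"))
  if (is.null(database)) database <- toy_database()
  if (!is.null(preset)) {
    spec <- preset_model(preset)
    cancers <- spec$cancers
    genes <- spec$genes
  }
  ped <- as_pedigree(pedigree)
  mdb <- build_model_database(database, cancers = cancers, genes = genes,
                              pedigree = ped)
  chk <- check_pedigree(ped, mdb)
  ped <- chk$pedigree
  space <- enumerate_genotypes(mdb$gene_variants, options$max_mut)

  imps <- impute_ages(ped, mdb, iterations = options$iterations,
                      seed = options$seed)
  one_pass <- function(p) {
    post <- peel(p, mdb, space, options)
    list(post = post, risk = future_risk(post, p, mdb, options))
  }
  passes <- if (options$parallel && length(imps) > 1L &&
                .Platform$OS.type == "unix") {
    cores <- max(1L, min(parallel::detectCores(logical = FALSE), length(imps)))
    parallel::mclapply(imps, one_pass, mc.cores = cores)
  } else {
    lapply(imps, one_pass)
  }

  posterior <- aggregate_imputations(lapply(passes, `[[`, "post"),
                                     value = "probability")
  risks <- lapply(passes, `[[`, "risk")
  future <- if (nrow(risks[[1]])) {
    aggregate_imputations(risks, value = "risk")
  } else {
    tibble(proband = integer(0), cancer = character(0), by_age = integer(0),
           estimate = numeric(0), lower = numeric(0), upper = numeric(0))
  }

  structure(
    list(posterior = posterior,
         future_risk = future,
         report = chk$report,
         cancers = mdb$cancers,
         gene_variants = mdb$gene_variants,
         genotypes = space$labels,
         max_mut = space$max_mut,
         iterations = length(imps),
         options = options),
    class = "mendel_risk")
}

#' @export
print.mendel_risk <- function(x, ...) {
  cat("<mendel_risk> ", length(unique(x$posterior$proband)), " proband(s), ",
      length(x$genotypes), " genotype states (max_mut = ", x$max_mut, "), ",
      x$iterations, " imputation pass(es)\n", sep = "")
  cat("\nPosterior carrier probabilities:\n")
  print(x$posterior, n = min(nrow(x$posterior), 12))
  if (nrow(x$future_risk)) {
    cat("\nFuture cancer risk:\n")
    print(x$future_risk, n = min(nrow(x$future_risk), 12))
  }
  invisible(x)
}

#' Tidy a fitted risk model
#'
#' @param x A `mendel_risk` object.
#' @param type `"posterior"` (default) for the carrier-probability table or
#'   `"risk"` for the future-risk table.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mendel_risk <- function(x, type = c("posterior", "risk"), ...) {
  type <- match.arg(type)
  if (type == "posterior") x$posterior else x$future_risk
}

#' One-row summary of a fitted risk model
#'
#' @param x A `mendel_risk` object.
#' @param ... Unused.
#' @return A tibble with one row per proband: the total carrier
#'   probability (1 minus the noncarrier posterior) with its imputation
#'   bounds, and the run's dimensions.
#' @export
glance.mendel_risk <- function(x, ...) {
  nc <- x$posterior[x$posterior$genotype == NONCARRIER, ]
  tibble(
    proband = nc$proband,
    carrier_probability = 1 - nc$estimate,
    carrier_lower = 1 - nc$upper,
    carrier_upper = 1 - nc$lower,
    n_genotypes = length(x$genotypes),
    n_cancers = length(x$cancers),
    n_genes = length(x$gene_variants),
    max_mut = x$max_mut,
    iterations = x$iterations)
}
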