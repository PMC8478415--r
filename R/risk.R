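# Future cancer risk from the genotype posterior.
#
# For a counselee who is free of cancer r at their censoring age C, the
# risk of developing it by age a = C + t0 mixes the genotype-specific
# conditional cumulative penetrances over the posterior:
#   risk(a) = sum_G P(G | H, U) * [F_G(a) - F_G(C)] / [1 - F_G(C)]
# where F_G is the cumulative CRUDE penetrance by default (the probability
# of developing the cancer without first dying of another cause), or the
# NET penetrance when requested. Conditioning on being cancer-free at C is
# applied per genotype, which makes the reported risk a proper conditional
# probability and keeps the mixture linear in the posterior.

#' Project future cancer risk for the probands
#'
#' @param posterior A single-pass posterior tibble from [peel()] (columns
#'   `proband`, `genotype`, `probability`).
#' @param ped The (checked, completed) pedigree the posterior was computed
#'   from; supplies each proband's censoring age, sex, race and affection
#'   status.
#' @param mdb A `model_database`.
#' @param options A [model_options()] list; `age_by` sets the reporting
#'   grid `C + age_by * k` (capped at 94) and `net` switches from crude to
#'   net penetrances.
#' @return A tibble with columns `proband`, `cancer`, `by_age`, `risk`.
#'   Cancers the proband has already had are omitted; probands with an
#'   unknown censoring age are skipped with a warning.
#' @export
future_risk <- function(posterior, ped, mdb, options = model_options()) {
  stopifnot(inherits(mdb, "model_database"))
  type <- if (isTRUE(options$net)) "Net" else "Crude"
  age_by <- as.integer(options$age_by %||% 5L)
  stopifnot(age_by >= 1L)
  out <- list()
  for (pid in unique(posterior$proband)) {
    row <- ped_row(ped, pid)
    if (!nrow(row)) next
    rec <- individual_record(row, mdb)
    if (!rec$cur_age_known || is.na(rec$cur_age)) {
      warning("proband ", pid, " has no observed current age; ",
              "future risk not computed", call. = FALSE)
      next
    }
    C <- min(rec$cur_age, MAX_AGE)
    grid <- seq.int(C + age_by, MAX_AGE, by = age_by)
    if (!length(grid)) next
    post <- posterior[posterior$proband == pid, ]
    post_p <- post$probability
    flags_list <- lapply(post$genotype, function(lab) resolve_flags(mdb, lab))
    for (r in seq_along(mdb$cancers)) {
      cancer <- mdb$cancers[r]
      if (!is.na(rec$aff[r]) && rec$aff[r] == 1L) next  # already affected
      risk_by_g <- vapply(flags_list, function(fl) {
        p <- genotype_curve(mdb, fl, cancer, rec$race, rec$sex, type, options,
                            rec$riskmod, rec$inter_age)
        cum <- cumsum(p)
        denom <- 1 - cum[C]
        if (denom <= 0) return(rep(0, length(grid)))
        (cum[grid] - cum[C]) / denom
      }, numeric(length(grid)))
      risk_by_g <- matrix(risk_by_g, nrow = length(grid))
      out[[length(out) + 1L]] <- tibble(
        proband = pid, cancer = cancer, by_age = as.integer(grid),
        risk = as.vector(risk_by_g %*% post_p))
    }
  }
  if (!length(out)) {
    return(tibble(proband = integer(0), cancer = character(0),
                  by_age = integer(0), risk = numeric(0)))
  }
  bind_rows(out)
}
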