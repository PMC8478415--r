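# Posterior carrier probabilities by Elston-Stewart peeling over the pared
# genotype space, plus an exact brute-force enumeration used as an oracle.
#
# The pedigree likelihood is represented as a factor graph with one genotype
# variable per "unit" (an individual, or a set of identical twins who share
# one genotype): founder units carry prior x likelihood factors, non-founder
# units carry transmission x likelihood factors over the (child, mother,
# father) triple. Peeling is sum-product variable elimination; on loop-free
# pedigrees the marriage graph is a tree, every intermediate factor stays
# small, and the result is exact on the pared space. Any valid elimination
# order gives the same marginal; the default order is greedy
# (smallest-intermediate-factor first) with deterministic tie-breaks.

# ---- internal family structure ----------------------------------------

fam_internal <- function(ped, mdb, space, opts) {
  ids <- ped$ID
  idx_of <- function(id) match(id, ids)

  # twin sets share one genotype variable
  unit_of <- seq_len(nrow(ped))
  tw <- ped$Twins
  for (g in setdiff(unique(tw[tw > 0L]), 0L)) {
    members <- which(tw == g)
    if (length(members) > 1L) unit_of[members] <- members[1L]
  }
  unit_ids <- unique(unit_of)
  unit_index <- match(unit_of, unit_ids)      # row -> unit number
  n_units <- length(unit_ids)

  mo <- idx_of(ped$MotherID)
  fa <- idx_of(ped$FatherID)
  if (any(!is.na(ped$MotherID) & is.na(mo)) ||
      any(!is.na(ped$FatherID) & is.na(fa))) {
    mr_error("pedigree refers to parent IDs that are not in the pedigree",
             "mendelrisk_validation_error")
  }
  one_parent <- xor(is.na(mo), is.na(fa))
  if (any(one_parent)) {
    mr_error(paste0("individual(s) ", paste(ids[one_parent], collapse = ", "),
                    " have exactly one recorded parent; run check_pedigree() ",
                    "to insert pseudo-parents first"),
             "mendelrisk_validation_error")
  }

  u_founder <- logical(n_units)
  u_mother <- u_father <- rep(NA_integer_, n_units)
  for (u in seq_len(n_units)) {
    rep_row <- match(unit_ids[u], seq_len(nrow(ped)))
    rows <- which(unit_index == u)
    # twins were checked to share parents; use the representative's
    r1 <- rows[1L]
    if (is.na(mo[r1])) {
      u_founder[u] <- TRUE
    } else {
      u_mother[u] <- unit_index[mo[r1]]
      u_father[u] <- unit_index[fa[r1]]
    }
  }

  L_rows <- likelihood_matrix(ped, space, mdb, opts)
  S <- space_size(space)
  L_units <- matrix(1, n_units, S)
  for (i in seq_len(nrow(ped))) {
    L_units[unit_index[i], ] <- L_units[unit_index[i], ] * L_rows[i, ]
  }

  priors <- matrix(NA_real_, n_units, S)
  for (u in which(u_founder)) {
    anc <- ped$Ancestry[which(unit_index == u)[1L]]
    priors[u, ] <- founder_prior(space, ancestry_freqs(mdb, anc))
  }

  probands <- which(ped$isProband == 1L)
  list(ped = ped, ids = ids, n_units = n_units, unit_index = unit_index,
       founder = u_founder, mother = u_mother, father = u_father,
       L = L_units, priors = priors,
       proband_ids = ids[probands],
       proband_units = unit_index[probands])
}

# ---- factor algebra ---------------------------------------------------

expand_factor_tab <- function(tab, vars, vars_u, S) {
  extra <- setdiff(vars_u, vars)
  if (length(vars) == 0L) {
    tab <- array(tab, dim = rep(S, length(vars_u)))
    return(tab)
  }
  if (length(extra)) {
    tab <- array(tab, dim = c(rep(S, length(vars)), rep(S, length(extra))))
  } else {
    tab <- array(tab, dim = rep(S, length(vars)))
  }
  ord <- c(vars, extra)
  aperm(tab, match(vars_u, ord))
}

factor_product <- function(f1, f2, S) {
  vars_u <- union(f1$vars, f2$vars)
  list(vars = vars_u,
       tab = expand_factor_tab(f1$tab, f1$vars, vars_u, S) *
             expand_factor_tab(f2$tab, f2$vars, vars_u, S))
}

factor_sum_out <- function(f, v, S) {
  pos <- match(v, f$vars)
  keep <- setdiff(seq_along(f$vars), pos)
  if (!length(keep)) {
    return(list(vars = character(0), tab = sum(f$tab)))
  }
  tab <- apply(array(f$tab, dim = rep(S, length(f$vars))), keep, sum)
  list(vars = f$vars[keep], tab = array(tab, dim = rep(S, length(keep))))
}

# Marginalize the factor list down to `target`, eliminating all other
# variables. Order: greedy, smallest resulting factor first; `order_perm`
# (a permutation of variable names) overrides for order-invariance checks.
eliminate_to <- function(factors, all_vars, target, S, order_perm = NULL) {
  to_go <- setdiff(all_vars, target)
  while (length(to_go)) {
    if (!is.null(order_perm)) {
      v <- intersect(order_perm, to_go)[1L]
    } else {
      width <- vapply(to_go, function(v) {
        length(Reduce(union, lapply(
          Filter(function(f) v %in% f$vars, factors), `[[`, "vars"))) - 1L
      }, integer(1))
      v <- to_go[which.min(width)]
    }
    touching <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(function(a, b) factor_product(a, b, S),
                     factors[touching])
    newf <- factor_sum_out(prod_f, v, S)
    # rescale for numerical range; the constant cancels on normalization
    mx <- max(newf$tab)
    if (is.finite(mx) && mx > 0) newf$tab <- newf$tab / mx
    factors <- c(factors[!touching], list(newf))
    to_go <- setdiff(to_go, v)
  }
  out <- Reduce(function(a, b) factor_product(a, b, S), factors)
  marg <- as.vector(expand_factor_tab(out$tab, out$vars, target, S))
  tot <- sum(marg)
  if (!is.finite(tot) || tot <= 0) {
    mr_error("pedigree has zero likelihood under the model (no genotype configuration is consistent with the data)",
             "mendelrisk_degenerate_error")
  }
  marg / tot
}

build_factors <- function(fam, space) {
  S <- space_size(space)
  tr <- NULL
  factors <- list()
  vnames <- paste0("u", seq_len(fam$n_units))
  for (u in seq_len(fam$n_units)) {
    if (fam$founder[u]) {
      factors[[length(factors) + 1L]] <-
        list(vars = vnames[u], tab = array(fam$priors[u, ] * fam$L[u, ], dim = S))
    } else {
      if (is.null(tr)) tr <- transmission_array(space)
      tab <- tr * rep(fam$L[u, ], times = S * S)  # scales T[c,m,f] by L(c)
      factors[[length(factors) + 1L]] <-
        list(vars = c(vnames[u], vnames[fam$mother[u]], vnames[fam$father[u]]),
             tab = tab)
    }
  }
  list(factors = factors, vnames = vnames)
}

# ---- public engines ---------------------------------------------------

#' Posterior carrier probabilities by pedigree peeling
#'
#' Computes, for every proband, the posterior distribution over the pared
#' genotype space given the whole family's cancer history — the
#' Elston-Stewart sum `P(G_1) * sum_{G_2..G_I} prod_i P(H_i | G_i, sex_i) *
#' P(G_2..G_I | G_1)`, normalized over the space. Identical twins are
#' constrained to share one genotype. The pedigree must already be checked
#' (two in-pedigree parents per non-founder, loop-free).
#'
#' @param ped A checked pedigree tibble (see [check_pedigree()]).
#' @param mdb A `model_database`.
#' @param space A `genotype_space` over the model's gene variants, or `NULL`
#'   to build it from `options$max_mut`.
#' @param options A [model_options()] list.
#' @return A tibble with columns `proband`, `genotype`, `probability`; the
#'   probabilities sum to 1 within each proband.
#' @seealso [brute_force_posterior()] for the exact enumeration oracle.
#' @export
peel <- function(ped, mdb, space = NULL, options = model_options()) {
  stopifnot(inherits(mdb, "model_database"))
  if (is.null(space)) {
    space <- enumerate_genotypes(mdb$gene_variants, options$max_mut)
  }
  loops <- detect_loops(ped)
  if (length(loops)) {
    mr_error("pedigree contains a loop; peeling is not supported on looped pedigrees",
             "mendelrisk_loop_error")
  }
  if (!any(ped$isProband == 1L)) {
    mr_error("pedigree has no proband", "mendelrisk_validation_error")
  }
  fam <- fam_internal(ped, mdb, space, options)
  bf <- build_factors(fam, space)
  S <- space_size(space)
  order_perm <- options$.elimination_order
  out <- vector("list", length(fam$proband_ids))
  for (j in seq_along(fam$proband_ids)) {
    target <- bf$vnames[fam$proband_units[j]]
    post <- eliminate_to(bf$factors, bf$vnames, target, S, order_perm)
    out[[j]] <- tibble(proband = fam$proband_ids[j],
                       genotype = space$labels,
                       probability = post)
  }
  bind_rows(out)
}

#' Exact posterior by brute-force genotype enumeration
#'
#' Enumerates every genotype configuration of the family over the pared
#' space and sums founder priors x transmissions x likelihoods directly.
#' Exponential in family size; it exists as an independent oracle for
#' [peel()] on small families.
#'
#' @inheritParams peel
#' @param guard Maximum number of genotype configurations to enumerate
#'   (default `1e7`).
#' @return A tibble with columns `proband`, `genotype`, `probability`.
#' @export
brute_force_posterior <- function(ped, mdb, space = NULL,
                                  options = model_options(), guard = 1e7) {
  stopifnot(inherits(mdb, "model_database"))
  if (is.null(space)) {
    space <- enumerate_genotypes(mdb$gene_variants, options$max_mut)
  }
  fam <- fam_internal(ped, mdb, space, options)
  S <- space_size(space)
  U <- fam$n_units
  n_conf <- S^U
  if (n_conf > guard) {
    mr_error(paste0("brute force would enumerate ", format(n_conf, big.mark = ","),
                    " configurations (guard: ", format(guard, big.mark = ","), ")"),
             "mendelrisk_size_error")
  }
  conf <- as.matrix(do.call(expand.grid, rep(list(seq_len(S)), U)))
  storage.mode(conf) <- "integer"
  logw <- numeric(nrow(conf))
  tr <- if (any(!fam$founder)) transmission_array(space) else NULL
  for (u in seq_len(U)) {
    logw <- logw + log(fam$L[u, ])[conf[, u]]
    if (fam$founder[u]) {
      logw <- logw + log(fam$priors[u, ])[conf[, u]]
    } else {
      flat <- conf[, u] + S * (conf[, fam$mother[u]] - 1L) +
        S * S * (conf[, fam$father[u]] - 1L)
      logw <- logw + log(tr)[flat]
    }
  }
  mx <- max(logw)
  if (!is.finite(mx)) {
    mr_error("pedigree has zero likelihood under the model (no genotype configuration is consistent with the data)",
             "mendelrisk_degenerate_error")
  }
  w <- exp(logw - mx)
  out <- vector("list", length(fam$proband_ids))
  for (j in seq_along(fam$proband_ids)) {
    u <- fam$proband_units[j]
    marg <- vapply(seq_len(S), function(s) sum(w[conf[, u] == s]), numeric(1))
    out[[j]] <- tibble(proband = fam$proband_ids[j],
                       genotype = space$labels,
                       probability = marg / sum(marg))
  }
  bind_rows(out)
}
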