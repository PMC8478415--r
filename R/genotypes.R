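# Pared multi-locus genotype space, founder priors and Mendelian
# transmission.
#
# A genotype is a vector of K binary carrier indicators, one per modelled
# gene. Paring truncates the space to genotypes carrying at most `max_mut`
# simultaneous mutations (the paring parameter, default 2), so the space has
# sum_{j<=max_mut} choose(K, j) states: the noncarrier first, then single
# carriers in gene order, then pairs in lexicographic order, and so on.
# Carriers are modelled as heterozygous for "any pathogenic variant" at
# unlinked autosomal loci: a carrier parent transmits the variant allele
# with probability 1/2, a noncarrier never does, and a child carries iff it
# receives at least one variant allele. Probability mass that Mendelian
# transmission would place on child genotypes outside the pared space is
# renormalized over the retained states, so every conditional stays a proper
# distribution.

#' Enumerate the pared genotype space
#'
#' @param genes Either an integer gene count `K` or a character vector of
#'   variant labels (length `K`).
#' @param max_mut Paring parameter: maximum number of simultaneous
#'   mutations. Values above `K` are clamped to `K` with a warning; `NULL`
#'   re-defaults to `min(2, K)`.
#' @return An object of class `genotype_space` with fields `flags` (an
#'   `S x K` 0/1 matrix), `labels` (`"noncarrier"` or dot-joined variant
#'   labels), `gene_variants` and `max_mut`.
#' @export
#' @examples
#' enumerate_genotypes(c("BRCA1_hetero_anyPV", "BRCA2_hetero_anyPV"), 2)$labels
enumerate_genotypes <- function(genes, max_mut = 2) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- paste0("gene", seq_len(genes))
  }
  genes <- as.character(genes)
  K <- length(genes)
  if (K < 1L) mr_error("at least one gene is required", "mendelrisk_validation_error")
  if (is.null(max_mut)) max_mut <- min(2L, K)
  max_mut <- as.integer(max_mut)
  if (max_mut < 1L) mr_error("max_mut must be at least 1", "mendelrisk_validation_error")
  if (max_mut > K) {
    warning("max_mut = ", max_mut, " exceeds the number of genes (", K,
            "); clamping to ", K, call. = FALSE)
    max_mut <- K
  }
  rows <- list(integer(K))
  for (j in seq_len(max_mut)) {
    combos <- combn(K, j)
    rows <- c(rows, lapply(seq_len(ncol(combos)), function(i) {
      f <- integer(K)
      f[combos[, i]] <- 1L
      f
    }))
  }
  flags <- do.call(rbind, rows)
  colnames(flags) <- genes
  labels <- apply(flags, 1, function(f) {
    if (!any(f == 1L)) NONCARRIER else paste(genes[f == 1L], collapse = ".")
  })
  structure(
    list(flags = flags, labels = unname(labels), gene_variants = genes,
         max_mut = max_mut),
    class = "genotype_space")
}

#' @export
print.genotype_space <- function(x, ...) {
  cat("<genotype_space> ", length(x$labels), " genotypes over ",
      length(x$gene_variants), " gene(s), max_mut = ", x$max_mut, "\n", sep = "")
  invisible(x)
}

space_size <- function(space) length(space$labels)

resolve_genotype_index <- function(space, g) {
  if (is.numeric(g) && length(g) == 1L && g == round(g) &&
      g >= 1 && g <= space_size(space)) {
    return(as.integer(g))
  }
  if (is.character(g)) {
    idx <- match(g, space$labels)
    if (!is.na(idx)) return(idx)
    mr_error(paste0("genotype label '", g, "' is not in the pared space"),
             "mendelrisk_lookup_error")
  }
  if (length(g) == ncol(space$flags)) {
    idx <- which(apply(space$flags, 1, function(f) all(f == g)))
    if (length(idx) == 1L) return(idx)
  }
  mr_error("cannot resolve genotype; give a label, index or carrier-flag vector",
           "mendelrisk_lookup_error")
}

# Per-genotype product of per-gene probabilities: p[k] when the flag is 1,
# q[k] when it is 0. Safe for p or q containing exact zeros.
flag_product <- function(flags, p, q) {
  out <- rep(1, nrow(flags))
  for (k in seq_len(ncol(flags))) {
    out <- out * ifelse(flags[, k] == 1L, p[k], q[k])
  }
  out
}

#' Founder genotype prior over the pared space
#'
#' Under Hardy-Weinberg equilibrium the per-gene carrier probability is
#' `2f(1-f) + f^2` for allele frequency `f`; the multi-locus prior is the
#' product over genes, renormalized over the retained (pared) genotypes.
#'
#' @param space A `genotype_space`.
#' @param freqs Numeric vector of allele frequencies, one per gene (in the
#'   space's gene order), resolved for the founder's ancestry.
#' @return Numeric vector of prior probabilities, summing to 1 over the
#'   space.
#' @export
founder_prior <- function(space, freqs) {
  K <- ncol(space$flags)
  if (length(freqs) == 1L) freqs <- rep(freqs, K)
  stopifnot(length(freqs) == K, all(freqs >= 0), all(freqs <= 0.5))
  carrier <- 2 * freqs * (1 - freqs) + freqs^2
  p <- flag_product(space$flags, carrier, 1 - carrier)
  p / sum(p)
}

# Child genotype distribution given parent genotype indices, renormalized
# over the pared space. Returns a length-S vector.
transmission_column <- function(space, m_idx, f_idx) {
  gm <- space$flags[m_idx, ]
  gf <- space$flags[f_idx, ]
  # P(child carries at gene k) = 1 - (1 - gm/2)(1 - gf/2)
  p1 <- gm / 2 + gf / 2 - gm * gf / 4
  v <- flag_product(space$flags, p1, 1 - p1)
  v / sum(v)
}

#' Mendelian transmission probability in the pared space
#'
#' Probability that a child has genotype `child` given parental genotypes,
#' under the heterozygous-carrier transmission model, renormalized over the
#' retained child genotypes.
#'
#' @param child,mother,father Genotypes, given as labels, indices into the
#'   space, or carrier-flag vectors.
#' @param space A `genotype_space` shared by all three.
#' @return A single probability. For fixed parents the probabilities over
#'   all child genotypes in the space sum to 1.
#' @export
transmission_prob <- function(child, mother, father, space) {
  ci <- resolve_genotype_index(space, child)
  mi <- resolve_genotype_index(space, mother)
  fi <- resolve_genotype_index(space, father)
  transmission_column(space, mi, fi)[ci]
}

# Full S x S x S transmission array T[child, mother, father], columns
# normalized over the pared child space. Guarded because the dense array is
# cubic in the space size.
transmission_array <- function(space) {
  S <- space_size(space)
  if (S > 150L) {
    mr_error(paste0("genotype space too large for a dense transmission array (",
                    S, " states); reduce the gene count or the paring parameter"),
             "mendelrisk_size_error")
  }
  tr <- array(0, dim = c(S, S, S))
  for (f in seq_len(S)) {
    for (m in seq_len(f)) {
      col <- transmission_column(space, m, f)
      tr[, m, f] <- col
      tr[, f, m] <- col  # symmetric in the parents
    }
  }
  tr
}
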