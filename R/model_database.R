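# Model database: the slice of a parameter database actually used by one
# model run — an ordered set of cancers and gene variants, with penetrance
# and allele-frequency lookups that apply the race (-> All_Races) and
# ancestry (-> nonAJ) fallbacks.

#' Build the model database for a run
#'
#' Resolves the requested cancers and genes against a parameter database and
#' subsets the penetrance and allele-frequency tables to them. Unset `genes`
#' defaults to every gene in the database; unset `cancers` defaults to the
#' cancers present in the pedigree's `isAff*` columns.
#'
#' @param db A `parameter_database`.
#' @param cancers Character vector of cancer labels (full names or short
#'   tags), or `NULL` for the pedigree's cancers.
#' @param genes Character vector of plain gene names (or variant labels), or
#'   `NULL` for all database genes.
#' @param pedigree Pedigree tibble, used only when `cancers` is `NULL`.
#' @return A list with class `model_database`: ordered `cancers`, `genes`,
#'   `gene_variants`, the subset `penetrance` and `allele_frequency` arrays,
#'   and the tag dictionary restricted to the model cancers.
#' @export
build_model_database <- function(db, cancers = NULL, genes = NULL,
                                 pedigree = NULL) {
  stopifnot(inherits(db, "parameter_database"))
  map <- db$gene_variant_map
  all_genes <- names(map)
  pen_dn <- dimnames(db$penetrance)

  if (is.null(genes)) {
    genes <- all_genes
  } else {
    genes <- vapply(as.character(genes), function(g) {
      if (g %in% all_genes) return(g)
      hit <- names(map)[match(g, map)]
      if (!is.na(hit)) return(hit)
      mr_error(paste0("unknown gene '", g, "'; valid genes: ",
                      paste(all_genes, collapse = ", ")),
               "mendelrisk_resolution_error")
    }, character(1), USE.NAMES = FALSE)
  }
  genes <- unique(genes)
  variants <- unname(map[genes])

  if (is.null(cancers)) {
    if (is.null(pedigree)) {
      mr_error("either cancers or a pedigree must be supplied",
               "mendelrisk_resolution_error")
    }
    tags <- pedigree_cancers(pedigree)
    if (!length(tags)) {
      mr_error("pedigree has no cancer history columns and no cancers were requested",
               "mendelrisk_resolution_error")
    }
    unknown <- setdiff(tags, names(db$cancer_tags))
    if (length(unknown)) {
      mr_error(paste0("pedigree cancer tag(s) not in the database dictionary: ",
                      paste(unknown, collapse = ", ")),
               "mendelrisk_resolution_error")
    }
    cancers <- unname(db$cancer_tags[tags])
  } else {
    cancers <- vapply(as.character(cancers), function(cc) {
      if (cc %in% pen_dn$Cancer) return(cc)
      if (cc %in% names(db$cancer_tags)) return(unname(db$cancer_tags[cc]))
      mr_error(paste0("unknown cancer '", cc, "'; valid cancers: ",
                      paste(pen_dn$Cancer, collapse = ", ")),
               "mendelrisk_resolution_error")
    }, character(1), USE.NAMES = FALSE)
  }
  cancers <- unique(cancers)
  missing_cancer <- setdiff(cancers, pen_dn$Cancer)
  if (length(missing_cancer)) {
    mr_error(paste0("cancer(s) absent from the penetrance table: ",
                    paste(missing_cancer, collapse = ", ")),
             "mendelrisk_resolution_error")
  }

  pen <- unclass(db$penetrance)[cancers, c(variants, NONCARRIER), , , , ,
                                drop = FALSE]
  af <- unclass(db$allele_frequency)[genes, , drop = FALSE]
  tags <- db$cancer_tags[db$cancer_tags %in% cancers]

  structure(
    list(cancers = cancers,
         genes = genes,
         gene_variants = variants,
         gene_variant_map = map[genes],
         cancer_tags = tags,
         penetrance = pen,
         allele_frequency = af),
    class = "model_database")
}

#' @export
print.model_database <- function(x, ...) {
  cat("<model_database> ", length(x$cancers), " cancer(s) - ",
      paste(x$cancers, collapse = ", "), "; ", length(x$genes),
      " gene(s) - ", paste(x$gene_variants, collapse = ", "), "\n", sep = "")
  invisible(x)
}

resolve_race <- function(mdb, race) {
  races <- dimnames(mdb$penetrance)$Race
  if (is.null(race) || is.na(race) || !race %in% races) "All_Races" else race
}

resolve_sex <- function(sex) {
  if (is.character(sex)) {
    if (!sex %in% SEXES) mr_error(paste0("unknown sex '", sex, "'"),
                                  "mendelrisk_lookup_error")
    return(sex)
  }
  if (!sex %in% c(0, 1)) mr_error("sex must be 0 (female) or 1 (male)",
                                  "mendelrisk_lookup_error")
  SEXES[sex + 1L]
}

resolve_variant <- function(mdb, genotype) {
  if (genotype %in% dimnames(mdb$penetrance)$Gene) return(genotype)
  if (genotype %in% names(mdb$gene_variant_map)) {
    return(unname(mdb$gene_variant_map[genotype]))
  }
  mr_error(paste0("unknown gene variant '", genotype, "'"),
           "mendelrisk_lookup_error")
}

# Full per-age penetrance curve (length MAX_AGE) for one slice.
penetrance_curve <- function(mdb, cancer, genotype, race, sex, type = "Net") {
  if (!cancer %in% mdb$cancers) {
    mr_error(paste0("cancer '", cancer, "' is not in the model"),
             "mendelrisk_lookup_error")
  }
  if (!type %in% PENET_TYPES) {
    mr_error("penetrance type must be 'Net' or 'Crude'", "mendelrisk_lookup_error")
  }
  mdb$penetrance[cancer, resolve_variant(mdb, genotype),
                 resolve_race(mdb, race), resolve_sex(sex), , type]
}

#' Look up an age-specific penetrance
#'
#' @param mdb A `model_database`.
#' @param cancer Cancer label in the model.
#' @param genotype A variant label, a plain gene name, or `"noncarrier"`.
#' @param race Race label; missing or off-axis races fall back to
#'   `All_Races`.
#' @param sex `"Female"`/`"Male"` or 0 (female) / 1 (male).
#' @param age Integer age in 1..94.
#' @param type `"Net"` (default) or `"Crude"`.
#' @return The penetrance value, a single probability.
#' @export
lookup_penetrance <- function(mdb, cancer, genotype, race = NA, sex, age,
                              type = "Net") {
  stopifnot(inherits(mdb, "model_database"))
  age <- as.integer(age)
  if (is.na(age) || age < 1L || age > MAX_AGE) {
    mr_error(paste0("age must be an integer in 1..", MAX_AGE),
             "mendelrisk_lookup_error")
  }
  unname(penetrance_curve(mdb, cancer, genotype, race, sex, type)[age])
}

#' Look up a pathogenic-variant allele frequency
#'
#' @param mdb A `model_database`.
#' @param gene Plain gene name (variant labels are accepted and mapped back).
#' @param ancestry `"AJ"`, `"nonAJ"` or `"Italian"`; missing falls back to
#'   `nonAJ`.
#' @return The allele frequency.
#' @export
lookup_allele_frequency <- function(mdb, gene, ancestry = NA) {
  stopifnot(inherits(mdb, "model_database"))
  if (!gene %in% rownames(mdb$allele_frequency)) {
    rev_hit <- names(mdb$gene_variant_map)[match(gene, mdb$gene_variant_map)]
    if (is.na(rev_hit)) {
      mr_error(paste0("unknown gene '", gene, "'"), "mendelrisk_lookup_error")
    }
    gene <- rev_hit
  }
  if (is.null(ancestry) || is.na(ancestry)) ancestry <- "nonAJ"
  if (!ancestry %in% ANCESTRIES) {
    mr_error(paste0("unknown ancestry '", ancestry, "'"),
             "mendelrisk_lookup_error")
  }
  unname(mdb$allele_frequency[gene, ancestry])
}

# Allele-frequency vector over the model genes for one ancestry.
ancestry_freqs <- function(mdb, ancestry = NA) {
  vapply(mdb$genes, lookup_allele_frequency, numeric(1), mdb = mdb,
         ancestry = ancestry)
}

#' Predefined single-syndrome model specifications
#'
#' Returns the cancers and genes of the classical single-syndrome Mendelian
#' models, so that e.g. a BRCAPRO-style run is exactly equivalent to the
#' explicit specification. `BRCAPRO6` extends BRCAPRO with the Lynch genes
#' and CDKN2A; `BRCAPRO5` is BRCAPRO6 without CDKN2A (a package convention:
#' the five-gene variant is not pinned down elsewhere).
#'
#' @param name One of `"BRCAPRO"`, `"BRCAPRO5"`, `"BRCAPRO6"`, `"MMRPRO"`.
#' @return A list with elements `cancers` and `genes`.
#' @export
#' @examples
#' preset_model("MMRPRO")
preset_model <- function(name) {
  presets <- list(
    BRCAPRO = list(cancers = c("Breast", "Ovarian"),
                   genes = c("BRCA1", "BRCA2")),
    BRCAPRO5 = list(cancers = c("Breast", "Ovarian"),
                    genes = c("BRCA1", "BRCA2", "MLH1", "MSH2", "MSH6")),
    BRCAPRO6 = list(cancers = c("Breast", "Ovarian"),
                    genes = c("BRCA1", "BRCA2", "MLH1", "MSH2", "MSH6", "CDKN2A")),
    MMRPRO = list(cancers = c("Colorectal", "Endometrial"),
                  genes = c("MLH1", "MSH2", "MSH6"))
  )
  if (!name %in% names(presets)) {
    mr_error(paste0("unknown preset '", name, "'; supported presets: ",
                    paste(names(presets), collapse = ", ")),
             "mendelrisk_resolution_error")
  }
  presets[[name]]
}
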