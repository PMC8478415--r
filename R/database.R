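# Parameter database: age-specific cancer penetrances and pathogenic-variant
# allele frequencies, with named axes.
#
# The penetrance table is a 6-way probability array indexed by
# (Cancer, Gene, Race, Sex, Age, PenetType). The Gene axis holds variant
# labels such as "BRCA1_hetero_anyPV" plus a dedicated "noncarrier" row (the
# baseline penetrance for carriers of none of the modelled variants). "Net"
# penetrances are P(T = t | G, sex) in a world without competing mortality;
# "Crude" penetrances are P(T* = t, J = 1 | G, sex), accounting for death
# from other causes. The allele-frequency table is (Gene x Ancestry) with
# plain gene names.
#
# On disk a database is a single JSON document with one object per table
# holding `dim`, `dimnames` and the column-major `values` vector — a
# language-neutral rendering of a dimnamed R array. See `write_database()`.

#' Construct a penetrance table
#'
#' @param values 6-way numeric array with dimnames
#'   `(Cancer, Gene, Race, Sex, Age, PenetType)`; `Sex` must be
#'   `Female`/`Male`, `Age` must cover 1..94 and `PenetType` must be
#'   `Net`/`Crude`. All values are probabilities and, for every fixed
#'   (cancer, gene, race, sex, type), the per-age probabilities must sum to
#'   at most 1.
#' @return The validated array with class `penetrance_table`.
#' @export
penetrance_table <- function(values) {
  dn <- dimnames(values)
  if (length(dim(values)) != 6L || is.null(dn) ||
      !identical(names(dn), c("Cancer", "Gene", "Race", "Sex", "Age", "PenetType"))) {
    mr_error(paste0("penetrance values must be a 6-way array with dimnames ",
                    "Cancer, Gene, Race, Sex, Age, PenetType"),
             "mendelrisk_validation_error")
  }
  if (!identical(dn$Sex, SEXES)) {
    mr_error("penetrance Sex axis must be 'Female', 'Male'",
             "mendelrisk_validation_error")
  }
  if (length(dn$Age) != MAX_AGE) {
    mr_error(paste0("penetrance Age axis must have length ", MAX_AGE),
             "mendelrisk_validation_error")
  }
  if (!identical(dn$PenetType, PENET_TYPES)) {
    mr_error("penetrance PenetType axis must be 'Net', 'Crude'",
             "mendelrisk_validation_error")
  }
  if (anyNA(values) || any(values < 0) || any(values > 1)) {
    mr_error("penetrance values must all lie in [0, 1]",
             "mendelrisk_validation_error")
  }
  sums <- apply(values, c(1, 2, 3, 4, 6), sum)
  bad <- which(sums > 1 + 1e-12, arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1, ]
    mr_error(sprintf(
      "penetrance slice (%s, %s, %s, %s, %s) sums to %.6f > 1 over ages",
      dn$Cancer[b[1]], dn$Gene[b[2]], dn$Race[b[3]], dn$Sex[b[4]],
      dn$PenetType[b[5]], sums[matrix(b, 1)]),
      "mendelrisk_validation_error")
  }
  structure(values, class = "penetrance_table")
}

#' Construct an allele-frequency table
#'
#' @param values Numeric matrix with dimnames `(Gene, Ancestry)`; ancestry
#'   levels must be `AJ`, `nonAJ`, `Italian` and all frequencies must lie in
#'   (0, 0.5].
#' @return The validated matrix with class `allele_frequency_table`.
#' @export
allele_frequency_table <- function(values) {
  dn <- dimnames(values)
  if (length(dim(values)) != 2L || is.null(dn) ||
      !identical(names(dn), c("Gene", "Ancestry"))) {
    mr_error("allele frequencies must be a (Gene x Ancestry) matrix",
             "mendelrisk_validation_error")
  }
  if (!identical(dn$Ancestry, ANCESTRIES)) {
    mr_error(paste0("allele-frequency Ancestry axis must be ",
                    paste(ANCESTRIES, collapse = ", ")),
             "mendelrisk_validation_error")
  }
  if (anyNA(values) || any(values <= 0) || any(values > 0.5)) {
    mr_error("allele frequencies must lie in (0, 0.5]",
             "mendelrisk_validation_error")
  }
  structure(values, class = "allele_frequency_table")
}

#' Assemble a parameter database
#'
#' @param penetrance A [penetrance_table()] (must include a `noncarrier`
#'   gene row).
#' @param allele_frequency An [allele_frequency_table()].
#' @param gene_variant_map Named character vector mapping plain gene names
#'   (the allele-frequency axis) to their default variant labels on the
#'   penetrance axis, e.g. `c(BRCA1 = "BRCA1_hetero_anyPV")`. Defaults to
#'   the `_hetero_anyPV` convention.
#' @param cancer_tags Named character vector mapping short cancer tags (the
#'   `isAff*` column suffixes) to penetrance Cancer labels.
#' @return A list with class `parameter_database`.
#' @export
parameter_database <- function(penetrance, allele_frequency,
                               gene_variant_map = NULL,
                               cancer_tags = CANCER_TAGS) {
  if (!inherits(penetrance, "penetrance_table")) {
    penetrance <- penetrance_table(penetrance)
  }
  if (!inherits(allele_frequency, "allele_frequency_table")) {
    allele_frequency <- allele_frequency_table(allele_frequency)
  }
  genes <- rownames(allele_frequency)
  if (is.null(gene_variant_map)) {
    gene_variant_map <- setNames(variant_label(genes), genes)
  }
  variants <- setdiff(dimnames(penetrance)$Gene, NONCARRIER)
  if (!NONCARRIER %in% dimnames(penetrance)$Gene) {
    mr_error("penetrance table must contain a 'noncarrier' gene row",
             "mendelrisk_validation_error")
  }
  if (!setequal(names(gene_variant_map), genes)) {
    mr_error("gene_variant_map names must match the allele-frequency genes",
             "mendelrisk_validation_error")
  }
  if (!setequal(unname(gene_variant_map), variants) ||
      anyDuplicated(unname(gene_variant_map))) {
    mr_error(paste0("gene_variant_map must be a bijection between genes and ",
                    "penetrance variant labels"),
             "mendelrisk_validation_error")
  }
  structure(
    list(penetrance = penetrance,
         allele_frequency = allele_frequency,
         gene_variant_map = gene_variant_map,
         cancer_tags = cancer_tags),
    class = "parameter_database")
}

#' @export
print.parameter_database <- function(x, ...) {
  dn <- dimnames(x$penetrance)
  cat("<parameter_database>\n")
  cat("  cancers:", length(dn$Cancer), "-", paste(head(dn$Cancer, 6), collapse = ", "),
      if (length(dn$Cancer) > 6) "..." else "", "\n")
  cat("  genes:  ", nrow(x$allele_frequency), "-",
      paste(head(rownames(x$allele_frequency), 6), collapse = ", "),
      if (nrow(x$allele_frequency) > 6) "..." else "", "\n")
  cat("  races:  ", paste(dn$Race, collapse = ", "), "\n")
  invisible(x)
}

array_to_json <- function(a) {
  list(dim = dim(a), dimnames = dimnames(a), values = as.vector(a))
}

json_to_array <- function(x, what) {
  if (is.null(x$values) || is.null(x$dim) || is.null(x$dimnames)) {
    mr_error(paste0("database container is missing the ", what, " table"),
             "mendelrisk_validation_error")
  }
  array(as.numeric(x$values), dim = as.integer(x$dim),
        dimnames = lapply(x$dimnames, as.character))
}

#' Load a parameter database from its JSON container
#'
#' The container is a single JSON document with members `Penetrance` and
#' `AlleleFrequency` (each an object with `dim`, `dimnames` and column-major
#' `values`), plus optional `GeneVariantMap` and `CancerTags` objects. All
#' type invariants (probabilities in \[0,1\], per-slice age sums at most 1,
#' 94-long age axis, frequency range) are validated on load.
#'
#' @param path Path to a database JSON file.
#' @return A `parameter_database`.
#' @seealso [write_database()], [make_toy_database()]
#' @export
load_database <- function(path) {
  if (!file.exists(path)) {
    mr_error(paste0("database file not found: ", path), "mendelrisk_io_error")
  }
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j$Penetrance)) {
    mr_error("database container is missing the Penetrance table",
             "mendelrisk_validation_error")
  }
  if (is.null(j$AlleleFrequency)) {
    mr_error("database container is missing the AlleleFrequency table",
             "mendelrisk_validation_error")
  }
  pen <- json_to_array(j$Penetrance, "Penetrance")
  af <- json_to_array(j$AlleleFrequency, "AlleleFrequency")
  map <- if (!is.null(j$GeneVariantMap)) unlist(j$GeneVariantMap) else NULL
  tags <- if (!is.null(j$CancerTags)) unlist(j$CancerTags) else CANCER_TAGS
  parameter_database(penetrance_table(pen), allele_frequency_table(af),
                     gene_variant_map = map, cancer_tags = tags)
}

#' Write a parameter database to its JSON container
#'
#' @param db A `parameter_database`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "parameter_database"))
  out <- list(
    Penetrance = array_to_json(unclass(db$penetrance)),
    AlleleFrequency = array_to_json(unclass(db$allele_frequency)),
    GeneVariantMap = as.list(db$gene_variant_map),
    CancerTags = as.list(db$cancer_tags)
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' The bundled toy parameter database
#'
#' Loads the small synthetic database shipped with the package (three genes,
#' two cancers, All_Races axis only). Its penetrance and allele-frequency
#' values are generated, not curated from the literature; it exists so that
#' examples and tests run without external data.
#'
#' @return A `parameter_database`.
#' @export
toy_database <- function() {
  load_database(system.file("extdata", "toy_database.json",
                            package = "mendelrisk", mustWork = TRUE))
}
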